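#' @include AllClasses.R utils.R
NULL

#' Percent change between two session scalars
#'
#' \code{100 * (v2 - v1) / v1}; session 1 is the baseline.
#'
#' @param v1 baseline scalar (nonzero)
#' @param v2 follow-up scalar
#' @return percent change
#' @examples
#' percentChange(100, 90)   # -10
#' @export
percentChange <- function(v1, v2) {
  if (v1 == 0) stop("percent change undefined for a zero baseline")
  100 * (v2 - v1) / v1
}

#' Shapiro-Wilk normality screen
#'
#' Advisory only: the between-session comparisons use the nonparametric
#' Mann-Whitney test regardless, but the normality screen is logged with
#' each comparison. Constant samples are flagged as degenerate instead of
#' producing a p-value.
#'
#' @param values numeric sample, n >= 3
#' @return list with \code{statistic}, \code{p}, and \code{degenerate}
#' @export
normalityCheck <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("normality check needs n >= 3")
  if (min(values) == max(values))
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  n <- length(values)
  if (n > 5000L) values <- values[seq(1L, n, length.out = 5000L)]
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p = sw$p.value, degenerate = FALSE)
}

# exact two-sided Mann-Whitney p by enumerating all C(n+m, n) group
# assignments of the pooled ranks (no ties)
.mwExactP <- function(u, n, m) {
  ranks <- seq_len(n + m)
  combos <- utils::combn(n + m, n)
  # U for sample a occupying ranks r: sum(r) - n(n+1)/2
  us <- colSums(matrix(ranks[combos], nrow = n)) - n * (n + 1) / 2
  pLe <- mean(us <= u + 1e-9)
  pGe <- mean(us >= u - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

#' Mann-Whitney U test (two-sided)
#'
#' \code{U = sum over pairs of [a_i > b_j] + 0.5 [a_i = b_j]}, computed via
#' pooled ranks. The p-value is exact (full enumeration of the
#' \code{choose(n + m, n)} rank assignments) when \code{min(n, m) <= 8} and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric samples, both non-empty
#' @return list with \code{U} (statistic for sample \code{a}), \code{p}
#'   (two-sided), and \code{exact} (logical)
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))   # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (min(n, m) <= 8L && !ties) {
    return(list(U = u, p = .mwExactP(u, n, m), exact = TRUE))
  }
  N <- n + m
  tt <- table(pooled)
  tieTerm <- sum(tt^3 - tt) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tieTerm)
  if (sigma2 <= 0) return(list(U = u, p = 1, exact = FALSE))
  mu <- n * m / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Sample mean and standard error of the mean
#'
#' SEM uses the sample (n - 1) standard deviation over sqrt(n).
#'
#' @param values numeric sample, n >= 2
#' @return list with \code{mean} and \code{sem}
#' @examples
#' meanSem(c(0, 2))   # mean 1, sem 1
#' @export
meanSem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("SEM undefined for n < 2")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}

#' Significance stars for a p-value
#'
#' p < 0.05 -> *, p < 0.01 -> **, p < 0.001 -> ***, otherwise ns.
#'
#' @param p p-value
#' @return one of "ns", "*", "**", "***"
#' @export
significanceStars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare metric distributions between two imaging sessions
#'
#' Distribution metrics (per-segment diameter, length, tortuosity,
#' inter-vessel distance, per-plaque radius, ...) are compared with
#' two-sided Mann-Whitney U tests, annotated with significance stars and
#' mean +/- SEM per session plus a Shapiro-Wilk normality screen. Scalar
#' totals (total vessel volume, total plaque volume) are reported as percent
#' change of session 2 versus session 1. Comparisons are unpaired: segments
#' are not tracked one-to-one across sessions. With \code{holm = TRUE} the
#' distribution p-values are Holm-adjusted across metrics (off by default,
#' matching per-metric reporting).
#'
#' @param session1,session2 named lists of numeric vectors; both sessions
#'   must provide the same metric names. Length-1 entries named in
#'   \code{scalarMetrics} are treated as scalar totals.
#' @param scalarMetrics names handled as scalars
#' @param holm apply Holm adjustment across distribution metrics?
#' @return data.frame with one row per metric: n per session, mean and SEM,
#'   Shapiro p per session, U, p, stars, percentChange (scalars: of the
#'   totals; distributions: of the means)
#' @export
compareSessions <- function(session1, session2,
                            scalarMetrics = c("vesselVolume", "plaqueVolume"),
                            holm = FALSE) {
  if (!setequal(names(session1), names(session2)))
    stop("sessions provide different metric sets: ",
         paste(symdiff <- union(setdiff(names(session1), names(session2)),
                                setdiff(names(session2), names(session1))),
               collapse = ", "))
  metrics <- names(session1)
  rows <- lapply(metrics, function(mname) {
    v1 <- as.numeric(session1[[mname]])
    v2 <- as.numeric(session2[[mname]])
    scalar <- mname %in% scalarMetrics
    if (scalar) {
      data.frame(metric = mname, type = "scalar",
                 n1 = length(v1), n2 = length(v2),
                 mean1 = mean(v1), sem1 = NA_real_,
                 mean2 = mean(v2), sem2 = NA_real_,
                 shapiroP1 = NA_real_, shapiroP2 = NA_real_,
                 U = NA_real_, p = NA_real_, stars = NA_character_,
                 percentChange = percentChange(mean(v1), mean(v2)))
    } else {
      ms1 <- meanSem(v1); ms2 <- meanSem(v2)
      nc1 <- normalityCheck(v1); nc2 <- normalityCheck(v2)
      mw <- mannWhitneyU(v1, v2)
      data.frame(metric = mname, type = "distribution",
                 n1 = length(v1), n2 = length(v2),
                 mean1 = ms1$mean, sem1 = ms1$sem,
                 mean2 = ms2$mean, sem2 = ms2$sem,
                 shapiroP1 = nc1$p, shapiroP2 = nc2$p,
                 U = mw$U, p = mw$p, stars = NA_character_,
                 percentChange = if (mean(v1) != 0)
                   percentChange(mean(v1), mean(v2)) else NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  isDist <- out$type == "distribution"
  if (holm && any(isDist))
    out$p[isDist] <- stats::p.adjust(out$p[isDist], method = "holm")
  out$stars[isDist] <- vapply(out$p[isDist], significanceStars, character(1))
  rownames(out) <- NULL
  out
}
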