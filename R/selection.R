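#' Rank model designs by summed BIC
#'
#' Sums each design's BIC over participants and ranks designs in ascending
#' order of summed BIC. Ties are broken by fewer free parameters, then by
#' design index.
#'
#' @param bic_matrix numeric matrix, participants x designs; no missing
#'   entries. Column names identify designs.
#' @param n_params optional integer vector of free-parameter counts per
#'   design (tie-break).
#' @param design_index optional integer vector of design indices (tie-break);
#'   defaults to column position.
#' @return An object of class `design_comparison`: the BIC matrix, summed BIC
#'   per design, and a ranking table.
#' @export
rank_designs <- function(bic_matrix, n_params = NULL, design_index = NULL) {
  bic_matrix <- as.matrix(bic_matrix)
  if (anyNA(bic_matrix)) {
    bad <- which(is.na(bic_matrix), arr.ind = TRUE)
    stop("missing fits for participant/design pairs: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "))
  }
  nd <- ncol(bic_matrix)
  if (is.null(design_index)) design_index <- seq_len(nd)
  if (is.null(n_params)) n_params <- rep(NA_integer_, nd)
  summed <- colSums(bic_matrix)
  ord <- order(summed, n_params, design_index)
  ranking <- data.frame(
    rank = seq_len(nd),
    design = if (!is.null(colnames(bic_matrix))) colnames(bic_matrix)[ord]
             else as.character(design_index[ord]),
    design_index = design_index[ord],
    n_params = n_params[ord],
    summed_bic = summed[ord],
    delta_bic = summed[ord] - min(summed),
    row.names = NULL)
  structure(list(bic = bic_matrix, summed_bic = summed, ranking = ranking),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("Design comparison over", nrow(x$bic), "participants\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Export a design comparison
#'
#' Writes the ranking table as CSV (the summed-BIC-by-design surface) and,
#' optionally, the full object as JSON.
#'
#' @param x a `design_comparison`.
#' @param csv,json output paths (`NULL` to skip either).
#' @return `x`, invisibly.
#' @export
write_design_comparison <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "design_comparison"))
  if (!is.null(csv))
    utils::write.csv(x$ranking, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(summed_bic = as.list(x$summed_bic),
                              ranking = x$ranking,
                              bic = as.data.frame(x$bic)),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Exact two-sided sign test
#'
#' Counts positive differences among the nonzero paired differences and
#' computes the exact two-sided binomial p-value by the doubling rule:
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with `X ~ Binomial(n, 1/2)`.
#' Zero differences are dropped.
#'
#' @param differences numeric vector of paired differences.
#' @return list with `statistic` (number of positive differences), `n`
#'   (nonzero differences), and `p.value`.
#' @export
#' @examples
#' sign_test(rep(1, 8))  # p = 2 * (1/2)^8
sign_test <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero; sign test undefined")
  k <- sum(d > 0)
  p <- min(1, 2 * min(pbinom(k, n, 0.5), pbinom(n - k, n, 0.5)))
  list(statistic = k, n = n, p.value = p)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests symmetry of `values` about `null_location`. Zeros (exact ties with
#' the null location) are dropped; tied absolute deviations receive midranks.
#' The p-value is exact (from the signed-rank distribution) for n <= 25
#' without ties, otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param values numeric vector.
#' @param null_location hypothesized center (default 0).
#' @return list with `statistic` (W+, sum of ranks of positive deviations),
#'   `n` (nonzero deviations), `z` (`NA` for the exact branch), `p.value`,
#'   and `method`.
#' @export
wilcoxon_signed_rank <- function(values, null_location = 0) {
  d <- values - null_location
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all deviations are zero; signed-rank test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    p <- min(1, 2 * min(psignrank(w, n),
                        psignrank(w - 1, n, lower.tail = FALSE)))
    return(list(statistic = w, n = n, z = NA_real_, p.value = p,
                method = "exact"))
  }
  e <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - e - 0.5 * sign(w - e)) / sqrt(v)
  list(statistic = w, n = n, z = z, p.value = 2 * pnorm(-abs(z)),
       method = "normal approximation")
}
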