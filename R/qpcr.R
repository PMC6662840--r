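#' Read a qPCR Ct table
#'
#' CSV or TSV with columns `sample_id`, `tissue`, `gene`, `ct` and an
#' optional `efficiency` (amplification factor per cycle, in \[1, 2\];
#' defaults to 2, i.e. perfect doubling).
#'
#' @param path input file; delimiter sniffed from the extension
#'   (`.csv` vs `.tsv`/`.txt`).
#' @return validated data.frame.
#' @export
readQpcrTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "gene", "ct")
  if (!all(need %in% colnames(df)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (!"efficiency" %in% colnames(df)) df$efficiency <- 2
  if (any(!is.finite(df$ct)) || any(df$ct < 0))
    stop("Ct values must be finite and >= 0")
  if (any(df$efficiency < 1 | df$efficiency > 2))
    stop("efficiency must lie in [1, 2]")
  df
}

#' Relative transcript quantity under the amplification-efficiency model
#'
#' The quantity of target relative to reference transcript in the same
#' sample is \eqn{E_t^{-Ct_t} / E_r^{-Ct_r}}, where E is the per-cycle
#' amplification factor (2 = 100% efficiency). With E = 2 for both genes
#' this reduces to the familiar \eqn{2^{Ct_r - Ct_t}} delta-Ct form. The
#' ratio is strictly decreasing in the target Ct and increasing in the
#' reference Ct.
#'
#' @param targetCt,referenceCt threshold cycles (vectorized).
#' @param targetE,referenceE amplification efficiencies in \[1, 2\].
#' @return numeric ratio(s) > 0.
#' @export
relativeQuantity <- function(targetCt, referenceCt, targetE = 2,
                             referenceE = 2) {
  if (any(c(targetE, referenceE) < 1) || any(c(targetE, referenceE) > 2))
    stop("efficiency must lie in [1, 2]")
  targetE^(-targetCt) / referenceE^(-referenceCt)
}

#' Per-sample relative expression of one gene against a reference gene
#'
#' Joins target and reference rows of a Ct table by `sample_id` and
#' applies [relativeQuantity()]. Samples must carry exactly one
#' measurement of each gene; a sample with a target but no reference
#' measurement (or vice versa) is a hard error.
#'
#' @param table Ct table (see [readQpcrTable()]).
#' @param target,reference gene symbols; must differ.
#' @return data.frame `sample_id`, `tissue`, `gene`, `ratio`.
#' @export
qpcrRelative <- function(table, target, reference) {
  if (identical(target, reference))
    stop("reference gene must differ from target")
  if (!"efficiency" %in% colnames(table)) table$efficiency <- 2
  tg <- table[table$gene == target, , drop = FALSE]
  rf <- table[table$gene == reference, , drop = FALSE]
  if (anyDuplicated(tg$sample_id) || anyDuplicated(rf$sample_id))
    stop("duplicated sample_id within a gene")
  i <- match(tg$sample_id, rf$sample_id)
  if (any(is.na(i)))
    stop("sample ids without a reference measurement: ",
         paste(tg$sample_id[is.na(i)], collapse = ", "))
  data.frame(sample_id = tg$sample_id, tissue = tg$tissue, gene = target,
             ratio = relativeQuantity(tg$ct, rf$ct[i], tg$efficiency,
                                      rf$efficiency[i]),
             stringsAsFactors = FALSE)
}

#' Normalize expression values to a fixed maximum (arbitrary units)
#'
#' Scales a vector of positive relative quantities so the maximum equals
#' `scale` exactly (default 10 a.u.); between-sample ratios are preserved.
#' Idempotent and scale-equivariant.
#'
#' @param values positive numeric vector (at least one positive value).
#' @param scale value assigned to the maximum.
#' @return numeric vector in \[0, scale\] with max exactly `scale`.
#' @export
normalizeToMax <- function(values, scale = 10) {
  if (!length(values) || all(values <= 0) || any(!is.finite(values)))
    stop("need at least one positive finite value")
  values * (scale / max(values))
}

#' Exact two-tailed Mann-Whitney U test
#'
#' The U statistic is computed from rank sums (midranks for ties). The
#' two-tailed p-value is exact - the full enumeration of all
#' \eqn{\binom{n_A+n_B}{n_A}} group labelings - when
#' \eqn{n_A + n_B \le 20} and the data carry no ties, doubling the smaller
#' one-sided tail and capping at 1. With ties or larger samples the normal
#' approximation with tie correction and continuity correction is used.
#' `exact = TRUE` forces enumeration even with ties (a midrank permutation
#' test); the automatic default refuses tied data to avoid ambiguity.
#'
#' @param a,b numeric vectors (each at least one value).
#' @param exact `NULL` (auto), `TRUE` or `FALSE`.
#' @return list with `U` (rank-sum statistic of group `a`), `p.value`, and
#'   `method` ("exact enumeration" or "normal approximation").
#' @export
mannWhitneyU <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups need at least one value")
  nA <- length(a); nB <- length(b); n <- nA + nB
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (n <= 20L && !ties)
  if (exact && n > 24L)
    stop("exact enumeration limited to n <= 24; set exact = FALSE")
  if (exact) {
    cmb <- utils::combn(n, nA)
    Uall <- colSums(matrix(r[cmb], nrow = nA)) - nA * (nA + 1) / 2
    eps <- sqrt(.Machine$double.eps)
    pLow <- mean(Uall <= U + eps)
    pHigh <- mean(Uall >= U - eps)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(U = U, p.value = p, method = "exact enumeration"))
  }
  mu <- nA * nB / 2
  tie <- table(pooled)
  tieCorr <- sum(tie^3 - tie) / (n * (n - 1))
  sigma <- sqrt(nA * nB / 12 * ((n + 1) - tieCorr))
  if (sigma == 0) return(list(U = U, p.value = 1,
                              method = "normal approximation"))
  z <- (abs(U - mu) - 0.5) / sigma
  z <- max(z, 0)
  list(U = U, p.value = min(1, 2 * stats::pnorm(-z)),
       method = "normal approximation")
}
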