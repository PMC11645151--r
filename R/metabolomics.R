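#' Impute missing metabolite abundances
#'
#' Missing values are assumed to fall below the detection limit and are
#' replaced, per metabolite (column), by 20% of that metabolite's minimum
#' observed value.
#'
#' @param matrix Numeric matrix or data frame, samples in rows, metabolites
#'   in columns; `NA` marks missing.
#' @return List with `matrix` (imputed) and `mask` (logical matrix of
#'   imputed positions).
#' @export
impute_metabolites <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(m < 0, na.rm = TRUE)) stop("abundances must be >= 0")
  mask <- is.na(m)
  fully <- colSums(!mask) == 0
  if (any(fully))
    stop("metabolite(s) with no observed value: ",
         paste(colnames(m)[fully] %||% which(fully), collapse = ", "))
  for (j in which(colSums(mask) > 0)) {
    m[mask[, j], j] <- 0.2 * min(m[!mask[, j], j])
  }
  list(matrix = m, mask = mask)
}

#' Average duplicate tissue sections per participant
#'
#' Each biopsy is measured on two sections; duplicate rows sharing a
#' participant id are averaged arithmetically (singletons pass through).
#'
#' @param matrix Numeric matrix, samples in rows, metabolites in columns.
#' @param participant_id Vector, one id per row.
#' @return Matrix with one row per participant (rownames = id, in first
#'   appearance order).
#' @export
average_duplicates <- function(matrix, participant_id) {
  m <- as.matrix(matrix)
  if (nrow(m) != length(participant_id))
    stop("participant_id must have one entry per row")
  ids <- unique(participant_id)
  out <- matrix(NA_real_, length(ids), ncol(m),
                dimnames = list(as.character(ids), colnames(m)))
  for (i in seq_along(ids))
    out[i, ] <- colMeans(m[participant_id == ids[i], , drop = FALSE])
  out
}

#' Percentage of atrophic tubules in a biopsy region
#'
#' @param n_atrophic,n_total Tubule counts; requires `n_total > 0` and
#'   `n_atrophic <= n_total`.
#' @return Percent of atrophic tubules.
#' @export
atrophic_tubule_fraction <- function(n_atrophic, n_total) {
  if (n_total <= 0) stop("total tubule count must be > 0")
  if (n_atrophic < 0 || n_atrophic > n_total)
    stop("atrophic count must lie in [0, n_total]")
  100 * n_atrophic / n_total
}
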