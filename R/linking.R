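# Linking drug modules to disease modules through curated chemical-disease
# associations.

#' Count curated associations crossing a module pair
#'
#' Counts distinct (drug, disease) pairs with the drug in the drug module,
#' the disease in the disease module, and a curated mark in `marks`. By
#' default any curated mark (`M`, `T`, `M&T`) qualifies; pass a subset to
#' restrict (e.g. `c("T", "M&T")` for therapeutic evidence only).
#'
#' @param drug_module character vector of drug identifiers.
#' @param disease_module character vector of disease identifiers.
#' @param curated a [curated_associations()] table.
#' @param marks curation marks that qualify as verified.
#' @return A nonnegative integer.
#' @export
count_cross_associations <- function(drug_module, disease_module, curated,
                                     marks = .KNOWN_MARKS) {
  if (!inherits(curated, "curated_associations")) {
    stopf("expected a curated_associations table")
  }
  hit <- curated$mark %in% marks &
    curated$chemical %in% drug_module &
    curated$disease %in% disease_module
  sum(hit)
}

#' Score the association between a drug module and a disease module
#'
#' The default score is the cross-association density
#' `M_ij / (N_i * N_j)`: the number of curated links crossing the pair,
#' normalized by the number of possible links, bounded in \[0, 1\] and zero
#' exactly when no curated link crosses. Alternative normalizations by the
#' sum (`M / (N_i + N_j)`) or geometric mean (`M / sqrt(N_i * N_j)`) of the
#' module sizes are selectable.
#'
#' @param M_ij number of curated cross associations.
#' @param N_i,N_j module sizes (at least 1).
#' @param formula normalization: `"product"` (default), `"sum"` or
#'   `"geomean"`.
#' @return A nonnegative number (in \[0, 1\] for `"product"`).
#' @examples
#' module_pair_score(5, 4, 4)  # 0.3125
#' @export
module_pair_score <- function(M_ij, N_i, N_j,
                              formula = c("product", "sum", "geomean")) {
  formula <- match.arg(formula)
  if (N_i < 1 || N_j < 1) stopf("module sizes must be at least 1")
  if (M_ij < 0 || M_ij > N_i * N_j) {
    stopf("M_ij = %d impossible for module sizes %d x %d", M_ij, N_i, N_j)
  }
  switch(formula,
         product = M_ij / (N_i * N_j),
         sum = M_ij / (N_i + N_j),
         geomean = M_ij / sqrt(N_i * N_j))
}

#' Score all (drug module, disease module) pairs
#'
#' @param drug_modules,disease_modules `module_set` objects (or named lists
#'   of member vectors).
#' @inheritParams count_cross_associations
#' @inheritParams module_pair_score
#' @return A data frame with one row per module pair: `drug_module_id`,
#'   `disease_module_id`, `M_ij`, `N_i`, `N_j`, `score`.
#' @export
link_modules <- function(drug_modules, disease_modules, curated,
                         formula = c("product", "sum", "geomean"),
                         marks = .KNOWN_MARKS) {
  formula <- match.arg(formula)
  dr <- if (inherits(drug_modules, "module_set"))
    module_members(drug_modules) else drug_modules
  di <- if (inherits(disease_modules, "module_set"))
    module_members(disease_modules) else disease_modules
  if (!length(dr) || !length(di)) stopf("both module sets must be non-empty")
  grid <- expand.grid(i = names(dr), j = names(di),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  M <- mapply(function(i, j) {
    count_cross_associations(dr[[i]], di[[j]], curated, marks)
  }, grid$i, grid$j)
  out <- data.frame(
    drug_module_id = grid$i,
    disease_module_id = grid$j,
    M_ij = as.integer(M),
    N_i = lengths(dr)[grid$i],
    N_j = lengths(di)[grid$j],
    stringsAsFactors = FALSE
  )
  out$score <- mapply(module_pair_score, out$M_ij, out$N_i, out$N_j,
                      MoreArgs = list(formula = formula))
  rownames(out) <- NULL
  out
}

#' Rank module pairs and keep the strongest
#'
#' Orders by descending score (ties broken lexicographically by drug then
#' disease module id), drops pairs scoring below `min_score` (the
#' comparison is inclusive: a pair scoring exactly `min_score` is kept),
#' then truncates to the `top_k` strongest.
#'
#' @param links the data frame from [link_modules()].
#' @param min_score minimum retained score (default 0.2).
#' @param top_k number of pairs to keep (default 3).
#' @return The filtered, ordered data frame.
#' @export
rank_module_pairs <- function(links, min_score = 0.2, top_k = 3) {
  if (min_score < 0) stopf("min_score must be nonnegative")
  if (top_k < 1) stopf("top_k must be at least 1")
  keep <- links[links$score >= min_score & links$score > 0, , drop = FALSE]
  keep <- keep[order(-keep$score, keep$drug_module_id,
                     keep$disease_module_id), , drop = FALSE]
  keep <- head(keep, top_k)
  rownames(keep) <- NULL
  keep
}
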