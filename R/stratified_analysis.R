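#' Requirement life-cycle chain distance
#'
#' Distance along the dynamic change pattern I -> A -> O(C) -> M, with
#' positions I=0, A=1, O=2, C=2, M=3 (One-dimensional and Critical share a
#' stage).
#'
#' @param a,b labels in `{I, A, O, C, M}` (vectorized, recycled).
#' @return non-negative integer vector of absolute stage differences.
#' @export
#' @examples
#' chain_distance("O", "C") # 0
#' chain_distance("I", "M") # 3
chain_distance <- function(a, b) {
  bad <- setdiff(unique(c(a, b)), names(CHAIN_POSITION))
  if (length(bad)) stop_ck("labels outside chain: ", paste(bad, collapse = ", "))
  abs(CHAIN_POSITION[a] - CHAIN_POSITION[b])
}

#' Map a demographic attribute onto analysis groups
#'
#' Helper for binary splits of multi-level demographics (e.g. income
#' brackets into low/high). The mapping is configuration, not statistics:
#' raw category labels map to group names; unmapped or missing values drop
#' the record from the stratification only.
#'
#' @param values character vector of raw demographic values.
#' @param mapping optional named character vector raw value -> group name;
#'   `NULL` uses the raw values as groups.
#' @return character vector of group names with `NA` for unmapped values.
#' @export
map_groups <- function(values, mapping = NULL) {
  if (is.null(mapping)) return(values)
  out <- unname(mapping[values])
  out
}

#' Stratified classification
#'
#' Runs the full pipeline (aggregate -> normalize -> thresholds ->
#' classify) independently inside each demographic subgroup. Because the
#' relative shares are normalized within a population, interval thresholds
#' are recomputed per subgroup by default; `pooled_thresholds = TRUE`
#' instead classifies every subgroup against the pooled-sample thresholds.
#'
#' @param rs a [kano_responses()] object.
#' @param attribute demographic column name present in the response data.
#' @param method `"candy"` or `"ratio"`.
#' @param v floating ratio for the interval classifier.
#' @param mapping optional raw-value -> group mapping (see [map_groups()]).
#' @param pooled_thresholds classify subgroups against pooled thresholds.
#' @return object of class `kano_stratified`: list with `attribute`,
#'   `groups` (named sizes), `labels` (items x groups data.frame), `flags`
#'   (TRUE where subgroup labels differ), `chain_dist` (max pairwise chain
#'   distance across groups per item) and `method`.
#' @export
stratify_classify <- function(rs, attribute, method = c("candy", "ratio"),
                              v = 1 / 6, mapping = NULL,
                              pooled_thresholds = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(rs, "kano_responses"))
  if (!attribute %in% names(rs$data)) {
    stop_ck("unknown attribute: ", attribute)
  }
  groups <- map_groups(rs$data[[attribute]], mapping)
  keep <- !is.na(groups)
  levels <- unique(groups[keep])
  if (length(levels) < 1L) stop_ck("no records carry attribute '", attribute, "'")
  pooled <- if (pooled_thresholds) {
    sub <- rs; sub$data <- rs$data[keep, , drop = FALSE]
    compute_thresholds(satisfaction_profile(sub), v)
  }
  per_group <- lapply(levels, function(g) {
    idx <- keep & groups == g
    if (!any(idx)) stop_ck("empty subgroup: ", g)
    sub <- rs
    sub$data <- rs$data[idx, , drop = FALSE]
    p <- satisfaction_profile(sub)
    classify_all(p, method, v = v, thresholds = pooled)
  })
  labels <- as.data.frame(stats::setNames(
    lapply(per_group, function(cl) cl$label), levels))
  rownames(labels) <- rs$catalog$code
  flags <- apply(labels, 1, function(x) length(unique(x)) > 1L)
  chain_dist <- apply(labels, 1, function(x) {
    pos <- CHAIN_POSITION[as.character(x)]
    as.integer(max(pos) - min(pos))
  })
  structure(list(attribute = attribute,
                 groups = stats::setNames(
                   vapply(levels, function(g) sum(keep & groups == g),
                          integer(1)), levels),
                 labels = labels, flags = flags, chain_dist = chain_dist,
                 method = method),
            class = "kano_stratified")
}

#' @export
print.kano_stratified <- function(x, ...) {
  cat("<kano_stratified> by '", x$attribute, "': ",
      paste(names(x$groups), x$groups, sep = "=", collapse = ", "),
      "; ", sum(x$flags), "/", length(x$flags), " items differ\n", sep = "")
  invisible(x)
}

#' Chain-adjacency summary of differentiated items
#'
#' Among items whose labels differ across subgroups, reports the fraction
#' whose labels stay within one stage of the requirement life-cycle chain
#' (upstream/downstream neighbours), and lists the violators.
#'
#' @param sc a [stratify_classify()] result, or a list with `flags` and
#'   `chain_dist` entries.
#' @return list with `n_flagged`, `fraction_adjacent` (`NA` when nothing is
#'   flagged) and `violators` (codes with chain distance > 1).
#' @export
adjacency_report <- function(sc) {
  flagged <- names(sc$flags)[sc$flags]
  if (!length(flagged)) {
    return(list(n_flagged = 0L, fraction_adjacent = NA_real_,
                violators = character()))
  }
  d <- sc$chain_dist[flagged]
  list(n_flagged = length(flagged),
       fraction_adjacent = mean(d <= 1L),
       violators = flagged[d > 1L])
}
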