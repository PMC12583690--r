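#' Answer-distribution archetype for a requirement category
#'
#' Operationalizes the qualitative response signatures of the five
#' categories as multinomial answer distributions, linearly interpolated
#' between uniform (strength 0) and the pure pattern (strength 1):
#' * C — forward mass on "Be fond of", reverse mass on "I don't like it"
#'   (high sensitivity in both directions);
#' * A — forward mass on "Be fond of", reverse uniform;
#' * M — forward uniform, reverse mass on "I don't like it";
#' * O — moderate mass on both extreme options (sensitive both ways, but
#'   less sharply than C);
#' * I — mass on the neutral option in both directions.
#'
#' @param label requirement category in `{C, M, O, A, I}`.
#' @param strength interpolation weight in `[0, 1]`.
#' @return list with `forward` and `reverse` probability 5-vectors.
#' @export
#' @examples
#' archetype("A", 0.5)$forward # 0.1 0.1 0.1 0.1 0.6
archetype <- function(label, strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  uniform <- rep(0.2, 5)
  pure <- switch(label,
    C = list(forward = c(0, 0, 0, 0, 1), reverse = c(1, 0, 0, 0, 0)),
    A = list(forward = c(0, 0, 0, 0, 1), reverse = uniform),
    M = list(forward = uniform, reverse = c(1, 0, 0, 0, 0)),
    O = list(forward = c(0.1, 0.1, 0.1, 0.2, 0.5),
             reverse = c(0.5, 0.2, 0.1, 0.1, 0.1)),
    I = list(forward = c(0, 0, 1, 0, 0), reverse = c(0, 0, 1, 0, 0)),
    stop_ck("unknown archetype label: ", label))
  mix <- function(p) (1 - strength) * uniform + strength * p
  list(forward = mix(pure$forward), reverse = mix(pure$reverse))
}

# Importance-rating distributions used when coupling importance to the
# planted category (sensitive categories rated more important).
IMPORTANCE_TARGETS <- list(
  C = c(0.00, 0.00, 0.05, 0.25, 0.70),
  M = c(0.00, 0.05, 0.15, 0.40, 0.40),
  O = c(0.00, 0.10, 0.20, 0.40, 0.30),
  A = c(0.05, 0.10, 0.30, 0.35, 0.20),
  I = c(0.20, 0.30, 0.30, 0.15, 0.05))

#' Synthetic questionnaire design
#'
#' Describes a population whose per-item answer distributions are planted
#' archetypes, optionally differing across demographic subgroups so that
#' stratified analyses have a known ground truth.
#'
#' @param catalog a [kano_catalog()].
#' @param labels named character vector item code -> planted category
#'   (recycled to all items when length 1).
#' @param strength archetype intensity in `[0, 1]`.
#' @param subgroup_sizes named numeric vector of subgroup weights (counts
#'   or proportions); a single unnamed value means one homogeneous group.
#' @param attribute demographic column carrying the subgroup membership.
#' @param overrides optional list `group -> (item code -> label)` replacing
#'   the planted label inside that subgroup.
#' @param importance_coupling in `[0, 1]`: 0 (default) draws importance
#'   ratings from `importance_base` independently of the Kano answers; 1
#'   draws them from a category-linked distribution, emulating the strong
#'   importance-sensitivity correlation seen in real data.
#' @param importance_base baseline importance distribution (5-vector).
#' @return object of class `kano_design`.
#' @export
synthetic_design <- function(catalog, labels, strength = 0.9,
                             subgroup_sizes = c(all = 1),
                             attribute = "role",
                             overrides = list(),
                             importance_coupling = 0,
                             importance_base = c(0.05, 0.10, 0.20, 0.35, 0.30)) {
  catalog <- kano_catalog(catalog)
  if (is.null(names(labels))) {
    if (length(labels) == 1L) labels <- rep(labels, nrow(catalog))
    if (length(labels) != nrow(catalog)) {
      stop_ck("unnamed labels must have length 1 or one per catalog item")
    }
    labels <- stats::setNames(labels, catalog$code)
  }
  miss <- setdiff(catalog$code, names(labels))
  if (length(miss)) stop_ck("no planted label for: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(labels), CANDY_LABELS)
  if (length(bad)) stop_ck("unknown labels: ", paste(bad, collapse = ", "))
  stopifnot(importance_coupling >= 0, importance_coupling <= 1,
            all(importance_base >= 0), length(importance_base) == 5)
  if (is.null(names(subgroup_sizes))) {
    names(subgroup_sizes) <- paste0("g", seq_along(subgroup_sizes))
  }
  for (g in names(overrides)) {
    if (!g %in% names(subgroup_sizes)) stop_ck("override for unknown group: ", g)
    bad <- setdiff(names(overrides[[g]]), catalog$code)
    if (length(bad)) stop_ck("override for unknown item: ", paste(bad, collapse = ", "))
  }
  structure(list(catalog = catalog, labels = labels[catalog$code],
                 strength = strength,
                 subgroup_sizes = subgroup_sizes / sum(subgroup_sizes),
                 attribute = attribute, overrides = overrides,
                 importance_coupling = importance_coupling,
                 importance_base = importance_base / sum(importance_base)),
            class = "kano_design")
}

# Effective planted label for an item inside a subgroup.
design_label <- function(d, group, code) {
  ov <- d$overrides[[group]]
  if (!is.null(ov) && code %in% names(ov)) ov[[code]] else d$labels[[code]]
}

design_importance_probs <- function(d, label) {
  w <- d$importance_coupling
  p <- (1 - w) * d$importance_base + w * IMPORTANCE_TARGETS[[label]]
  p / sum(p)
}

#' Generate a synthetic response set
#'
#' Draws `q` independent respondents from the design's multinomials. The
#' same seed always reproduces the same response set; subgroup membership
#' is assigned deterministically in proportion to the design's subgroup
#' sizes (largest-remainder rounding).
#'
#' @param d a [synthetic_design()].
#' @param q number of respondents, `q >= 1`.
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @return a [kano_responses()] object in the canonical schema.
#' @export
generate_responses <- function(d, q, seed = NULL) {
  stopifnot(inherits(d, "kano_design"), q >= 1)
  groups <- names(d$subgroup_sizes)
  base <- floor(q * d$subgroup_sizes)
  rem <- q - sum(base)
  if (rem > 0) {
    frac <- q * d$subgroup_sizes - base
    extra <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  membership <- rep(groups, times = base)
  with_seed(seed, {
    df <- data.frame(respondent_id = sprintf("R%05d", seq_len(q)),
                     stringsAsFactors = FALSE)
    df[[d$attribute]] <- membership
    codes <- d$catalog$code
    for (code in codes) {
      f <- r <- imp <- integer(q)
      for (g in groups) {
        idx <- which(membership == g)
        if (!length(idx)) next
        lab <- design_label(d, g, code)
        probs <- archetype(lab, d$strength)
        f[idx] <- sample.int(5L, length(idx), replace = TRUE,
                             prob = probs$forward)
        r[idx] <- sample.int(5L, length(idx), replace = TRUE,
                             prob = probs$reverse)
        imp[idx] <- sample.int(5L, length(idx), replace = TRUE,
                               prob = design_importance_probs(d, lab))
      }
      df[[paste0(code, "_f")]] <- f
      df[[paste0(code, "_r")]] <- r
      df[[paste0(code, "_imp")]] <- imp
    }
    schema <- response_schema(d$catalog, demographics = d$attribute)
    kano_responses(df, d$catalog, schema)
  })
}

#' Planted-label recovery experiment
#'
#' Generates `reps` independent populations from a design and measures, per
#' item, the fraction of replicates in which the interval classifier
#' recovers the planted category. This is the validation harness for the
#' classifier: with separated archetypes and growing `q`, recovery
#' approaches 1.
#'
#' @param d a [synthetic_design()].
#' @param q respondents per replicate.
#' @param reps number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param v floating ratio passed to the classifier.
#' @return list with `per_item` (named recovery fractions), `mean_recovery`
#'   and the run parameters.
#' @export
recovery_experiment <- function(d, q, reps, seed = 1, v = 1 / 6) {
  stopifnot(inherits(d, "kano_design"), reps >= 1)
  seeds <- derive_seeds(seed, reps)
  hits <- matrix(0L, nrow = nrow(d$catalog), ncol = reps,
                 dimnames = list(d$catalog$code, NULL))
  for (i in seq_len(reps)) {
    rs <- generate_responses(d, q, seed = seeds[i])
    cl <- classify_all(satisfaction_profile(rs), "candy", v = v)
    hits[, i] <- as.integer(cl$label == d$labels[cl$code])
  }
  per_item <- rowMeans(hits)
  list(per_item = per_item, mean_recovery = mean(per_item),
       q = q, reps = reps, strength = d$strength, seed = seed)
}
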