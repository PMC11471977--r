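# Diversity statistics on incidence matrices: richness and endemism per
# unit, Jaccard similarity with UPGMA clustering, species accumulation
# curves (exact hypergeometric expectation and permutation), first- and
# second-order jackknife richness estimators, and Poisson regression of
# richness on basin area.

#' Build an incidence matrix
#'
#' Collapses assigned occurrence records to a sampling-unit x species
#' presence/absence matrix. Units can be sub-basins, grid cells, or years
#' (for accumulation with years as samples). Records without an assignment,
#' without an accepted name, or (for `unit = year`) without a year are
#' dropped from the matrix only.
#'
#' @param records Occurrence tibble with `accepted_name` filled.
#' @param unit Either the name of a column in `records` (e.g. `"year"`) or
#'   an assignment tibble from [assign_records()] (joined on `record_id`).
#' @return An object of class `incidence_matrix`: list with `presence`
#'   (logical unit x species matrix), `units`, `species`, `m` (number of
#'   units), `m_i` (per-species incidence counts), `Q1`, `Q2`, `S_obs`.
#' @export
build_incidence <- function(records, unit) {
  if (is.data.frame(unit)) {
    df <- dplyr::inner_join(
      records[, c("record_id", "accepted_name")],
      unit, by = "record_id")
    df <- df[!is.na(df$region_id) & !is.na(df$accepted_name), ]
    u <- df$region_id
  } else {
    stopifnot(is.character(unit), unit %in% names(records))
    df <- records[!is.na(records[[unit]]) & !is.na(records$accepted_name), ]
    u <- as.character(df[[unit]])
  }
  units <- sort(unique(u))
  species <- sort(unique(df$accepted_name))
  presence <- matrix(FALSE, nrow = length(units), ncol = length(species),
                     dimnames = list(units, species))
  if (nrow(df) > 0) {
    presence[cbind(match(u, units), match(df$accepted_name, species))] <- TRUE
  }
  new_incidence_matrix(presence)
}

#' Construct an incidence matrix from a logical matrix
#'
#' @param presence Logical unit x species matrix (rows = sampling units).
#' @return An `incidence_matrix` with derived counts `m`, `m_i`, `Q1`, `Q2`,
#'   `S_obs`.
#' @export
new_incidence_matrix <- function(presence) {
  storage.mode(presence) <- "logical"
  m_i <- colSums(presence)
  structure(list(
    presence = presence,
    units = rownames(presence),
    species = colnames(presence),
    m = nrow(presence),
    m_i = m_i,
    Q1 = sum(m_i == 1),
    Q2 = sum(m_i == 2),
    S_obs = sum(m_i >= 1)
  ), class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d units x %d species (S_obs = %d, Q1 = %d, Q2 = %d)\n",
              x$m, length(x$species), x$S_obs, x$Q1, x$Q2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an incidence matrix into long form
#'
#' @param x An `incidence_matrix`.
#' @param ... Unused.
#' @return Tibble `unit`, `species` for each presence.
#' @export
tidy.incidence_matrix <- function(x, ...) {
  idx <- which(x$presence, arr.ind = TRUE)
  tibble::tibble(unit = x$units[idx[, 1]], species = x$species[idx[, 2]]) |>
    dplyr::arrange(.data$unit, .data$species)
}

#' Per-unit richness and endemism
#'
#' Richness is the number of species present in a unit; the endemic count
#' uses the strict definition that a species' documented distribution is the
#' target biome and nothing else (`biome_codes` identically `{"AM"}`).
#'
#' @param x An `incidence_matrix` over spatial units.
#' @param taxonomy A `taxon_table`.
#' @param target_code Biome code defining endemism (default `"AM"`).
#' @return Tibble `unit`, `richness`, `endemic_count`.
#' @export
richness_endemism <- function(x, taxonomy, target_code = "AM") {
  idx <- match(x$species, taxonomy$accepted_name)
  endemic <- !is.na(idx) & vapply(seq_along(idx), function(k) {
    if (is.na(idx[k])) return(FALSE)
    identical(sort(taxonomy$biome_codes[[idx[k]]]), target_code)
  }, logical(1))
  tibble::tibble(
    unit = x$units,
    richness = as.integer(rowSums(x$presence)),
    endemic_count = as.integer(rowSums(x$presence[, endemic, drop = FALSE]))
  )
}

#' Jaccard similarity between sampling units
#'
#' `J(A, B) = |S_A intersect S_B| / |S_A union S_B|` on the units' species
#' sets. Two empty units are defined to have similarity 1 (with a warning).
#'
#' @param x An `incidence_matrix` with at least 2 units.
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
jaccard_similarity <- function(x) {
  if (x$m < 2) stop("need at least 2 units for similarity", call. = FALSE)
  p <- x$presence * 1
  shared <- p %*% t(p)
  sizes <- rowSums(p)
  union <- outer(sizes, sizes, `+`) - shared
  if (any(union == 0)) {
    warning("empty units present; J(empty, empty) defined as 1", call. = FALSE)
  }
  j <- ifelse(union == 0, 1, shared / union)
  diag(j) <- 1
  dimnames(j) <- list(x$units, x$units)
  j
}

#' UPGMA clustering of units by compositional similarity
#'
#' Average-linkage (UPGMA) agglomeration on the Jaccard distance
#' `1 - J`. Returns a standard [stats::hclust] tree whose merge heights are
#' non-decreasing.
#'
#' @param similarity A similarity matrix from [jaccard_similarity()].
#' @return An `hclust` object.
#' @export
upgma_cluster <- function(similarity) {
  stopifnot(isSymmetric(unname(similarity)))
  d <- stats::as.dist(1 - similarity)
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram at a similarity threshold
#'
#' Groups are the connected clusters whose internal merges all happen at
#' distance `< 1 - min_similarity` (i.e. similarity above the threshold).
#'
#' @param dendrogram An `hclust` tree from [upgma_cluster()].
#' @param min_similarity Similarity threshold (default 0.40, the background
#'   level below which basin compositions are considered unrelated).
#' @return Tibble `unit`, `group` (integer group labels).
#' @export
cut_dendrogram <- function(dendrogram, min_similarity = 0.40) {
  grp <- stats::cutree(dendrogram, h = 1 - min_similarity - 1e-12)
  tibble::tibble(unit = names(grp), group = as.integer(grp))
}

#' Species accumulation curve
#'
#' Expected species count when `t` of the `m` sampling units are examined.
#' `method = "exact"` uses the closed-form hypergeometric expectation
#' `E[S(t)] = sum_i (1 - C(m - m_i, t) / C(m, t))`; `method = "permutation"`
#' averages over `n_perm` random unit orderings and also returns the 2.5%
#' and 97.5% quantiles across permutations.
#'
#' @param x An `incidence_matrix`.
#' @param method `"exact"` (default) or `"permutation"`.
#' @param n_perm Number of permutations (permutation method).
#' @param seed Seed for the permutation draw (required for that method).
#' @return Tibble `t`, `richness`, and for permutations `lower`, `upper`.
#' @export
accumulation_curve <- function(x, method = c("exact", "permutation"),
                               n_perm = 100, seed = NULL) {
  method <- match.arg(method)
  m <- x$m
  if (m < 1) stop("need at least one sampling unit", call. = FALSE)
  if (method == "exact") {
    richness <- vapply(seq_len(m), function(t) {
      # log-scale binomial ratio; C(m - m_i, t) = 0 when t > m - m_i
      p_absent <- ifelse(x$m_i > m - t, 0,
                         exp(lchoose(m - x$m_i, t) - lchoose(m, t)))
      sum(1 - p_absent)
    }, numeric(1))
    return(tibble::tibble(t = seq_len(m), richness = richness))
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("permutation method needs a seed", call. = FALSE)
  curves <- withr::with_seed(seed, {
    replicate(n_perm, {
      ord <- sample.int(m)
      cum <- apply(x$presence[ord, , drop = FALSE], 2, cummax)
      rowSums(matrix(cum, nrow = m))
    })
  })
  tibble::tibble(
    t = seq_len(m),
    richness = rowMeans(curves),
    lower = apply(curves, 1, stats::quantile, 0.025),
    upper = apply(curves, 1, stats::quantile, 0.975)
  )
}

#' Jackknife richness estimators (orders 1 and 2)
#'
#' Incidence-based richness estimation from the counts of species seen in
#' exactly one (`Q1`) and exactly two (`Q2`) sampling units:
#' \deqn{\hat{S}_{jack1} = S_{obs} + Q_1 \frac{m-1}{m}}
#' \deqn{\hat{S}_{jack2} = S_{obs} + Q_1 \frac{2m-3}{m} - Q_2 \frac{(m-2)^2}{m(m-1)}}
#'
#' @param x An `incidence_matrix` with at least 2 units.
#' @return Object of class `richness_estimate` (list with `S_obs`, `jack1`,
#'   `jack2`, `m`, `Q1`, `Q2`); see [glance.richness_estimate()].
#' @export
jackknife2 <- function(x) {
  m <- x$m
  if (m < 2) stop("jackknife estimators are undefined for m < 2", call. = FALSE)
  jack1 <- x$S_obs + x$Q1 * (m - 1) / m
  jack2 <- x$S_obs + x$Q1 * (2 * m - 3) / m - x$Q2 * (m - 2)^2 / (m * (m - 1))
  structure(list(S_obs = x$S_obs, jack1 = jack1, jack2 = jack2,
                 m = m, Q1 = x$Q1, Q2 = x$Q2),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("<richness_estimate> S_obs = %d, jack1 = %.1f, jack2 = %.1f (m = %d)\n",
              x$S_obs, x$jack1, x$jack2, x$m))
  invisible(x)
}

#' One-row summary of a richness estimate
#'
#' @param x A `richness_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the observed and estimated richness and the
#'   observed share of the second-order estimate.
#' @export
glance.richness_estimate <- function(x, ...) {
  tibble::tibble(
    S_obs = x$S_obs, jack1 = x$jack1, jack2 = x$jack2,
    m = x$m, Q1 = x$Q1, Q2 = x$Q2,
    completeness_pct = percent(x$S_obs, x$jack2, 1)
  )
}

#' Poisson regression of richness on unit area
#'
#' Log-link Poisson GLM of per-unit species richness on basin area, the
#' standard species-area model for count responses. The covariate defaults
#' to `log(area)`; raw area is available. Fitting is by iteratively
#' reweighted least squares via [stats::glm()].
#'
#' @param data Data frame with one row per unit.
#' @param richness,area_km2 Column names (strings) of the response and area.
#' @param covariate `"log_area"` (default) or `"area"`.
#' @return Object of class `richness_area_fit` wrapping the `glm` fit; use
#'   [tidy.richness_area_fit()] / [glance.richness_area_fit()].
#' @export
poisson_glm <- function(data, richness = "richness", area_km2 = "area_km2",
                        covariate = c("log_area", "area")) {
  covariate <- match.arg(covariate)
  if (nrow(data) < 3) stop("need at least 3 units to fit", call. = FALSE)
  y <- data[[richness]]
  a <- data[[area_km2]]
  if (any(a <= 0)) stop("areas must be positive", call. = FALSE)
  x <- if (covariate == "log_area") log(a) else a
  df <- data.frame(y = y, x = x)
  fit <- stats::glm(y ~ x, family = stats::poisson(), data = df,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop("Poisson GLM did not converge in 100 IRLS iterations", call. = FALSE)
  }
  structure(list(fit = fit, covariate = covariate), class = "richness_area_fit")
}

#' @export
print.richness_area_fit <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Coefficient table for a richness-area fit
#'
#' @param x A `richness_area_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std_error`, `z`, `p_value`.
#' @export
tidy.richness_area_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", x$covariate),
    estimate = cf[, 1],
    std_error = cf[, 2],
    z = cf[, 3],
    p_value = cf[, 4]
  )
}

#' Fit-level summary for a richness-area fit
#'
#' @param x A `richness_area_fit`.
#' @param ... Unused.
#' @return One-row tibble with deviance, null deviance, AIC and n.
#' @export
glance.richness_area_fit <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance,
    deviance = stats::deviance(x$fit),
    aic = stats::AIC(x$fit),
    n = stats::nobs(x$fit)
  )
}

#' Write a dendrogram as Newick text
#'
#' @param dendrogram An `hclust` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  labs <- dendrogram$labels
  h <- dendrogram$height
  node_txt <- character(nrow(dendrogram$merge))
  node_h <- numeric(nrow(dendrogram$merge))
  txt_of <- function(k) if (k < 0) list(txt = labs[-k], h = 0) else
    list(txt = node_txt[k], h = node_h[k])
  for (i in seq_len(nrow(dendrogram$merge))) {
    a <- txt_of(dendrogram$merge[i, 1])
    b <- txt_of(dendrogram$merge[i, 2])
    node_txt[i] <- sprintf("(%s:%.6f,%s:%.6f)",
                           a$txt, h[i] / 2 - a$h / 2,
                           b$txt, h[i] / 2 - b$h / 2)
    node_h[i] <- h[i]
  }
  writeLines(paste0(node_txt[length(node_txt)], ";"), path)
  invisible(path)
}
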