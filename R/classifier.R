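# Radius-neighbors classification of species composition to forest type.
#
# One classifier per supersection, trained on (fractional-basal-area vector,
# forest-type code) pairs from inventory conditions. The neighborhood radius
# is chosen by grid search with stratified k-fold cross-validation, maximizing
# the class-support-weighted F1 score; ties break toward the smallest radius.
# Classification of a query returns, for each forest type, the share of
# training vectors of that type among all training vectors within the radius
# (Euclidean distance); a query with no neighbors inside the radius falls back
# to its single nearest neighbor with probability 1.

#' Default radius grid: 21 values geometrically spaced in [0.05, 1.5]
#' @return Numeric vector of candidate radii.
#' @export
default_radius_grid <- function() {
  exp(seq(log(0.05), log(1.5), length.out = 21))
}

#' Embed a supersection's conditions as training pairs
#'
#' Species axes are the sorted union of species observed in the supersection's
#' conditions; each condition becomes a vector over those axes (absent species
#' contribute 0) labeled with its forest-type code.
#'
#' @param conditions Inventory condition table.
#' @param supersection Supersection identifier to subset to.
#' @return List with `x` (numeric matrix, conditions by species axes) and
#'   `labels` (character vector of forest-type codes).
#' @export
build_training_pairs <- function(conditions, supersection) {
  sub <- conditions[conditions$supersection == supersection, ]
  if (nrow(sub) == 0) {
    abort(sprintf("no conditions in supersection '%s': cannot fit", supersection))
  }
  axes <- sort(unique(unlist(lapply(sub$species_fractions, names))))
  x <- matrix(0, nrow(sub), length(axes), dimnames = list(NULL, axes))
  for (i in seq_len(nrow(sub))) {
    fr <- sub$species_fractions[[i]]
    x[i, names(fr)] <- fr
  }
  list(x = x, labels = sub$forest_type)
}

# Squared Euclidean distances between rows of q and rows of x
cross_dist2 <- function(q, x) {
  d2 <- outer(rowSums(q^2), rowSums(x^2), `+`) - 2 * q %*% t(x)
  pmax(d2, 0)
}

# Hard label prediction for a query matrix: radius vote, nearest-neighbor
# fallback, ties toward the lexicographically smallest label.
predict_labels <- function(x, labels, q, radius) {
  d2 <- cross_dist2(q, x)
  r2 <- radius^2 + 1e-12
  apply(d2, 1, function(row) {
    nb <- which(row <= r2)
    if (length(nb) == 0) nb <- which.min(row)
    tab <- table(labels[nb])
    names(tab)[which.max(tab)]
  })
}

stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Fit a per-supersection radius-neighbors forest-type classifier
#'
#' Selects the neighborhood radius by grid search with stratified k-fold
#' cross-validation, scoring each fold's held-out predictions with the
#' class-support-weighted F1 and averaging over folds; ties break toward the
#' smallest radius. With a single forest type present no radius matters: the
#' model predicts that type with probability 1 and score 1.0 (logged).
#'
#' @param conditions Inventory condition table.
#' @param supersection Supersection to fit.
#' @param radius_grid Candidate radii (default [default_radius_grid()]).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `ft_classifier`.
#' @export
fit_classifier <- function(conditions, supersection,
                           radius_grid = default_radius_grid(),
                           n_folds = 5, seed = 1L) {
  stopifnot(length(radius_grid) >= 1, all(radius_grid > 0), n_folds >= 2)
  pairs <- build_training_pairs(conditions, supersection)
  x <- pairs$x
  labels <- pairs$labels
  radius_grid <- sort(radius_grid)

  if (length(unique(labels)) == 1) {
    inform(sprintf(
      "supersection '%s' has a single forest type '%s': degenerate classifier",
      supersection, labels[1]), class = "recredit_log")
    return(structure(
      list(supersection = supersection, species_axes = colnames(x), x = x,
           labels = labels, radius = min(radius_grid),
           cv_radius_grid = radius_grid,
           cv = tibble(radius = radius_grid, mean_f1 = 1),
           selected_score = 1, single_label = TRUE),
      class = "ft_classifier"))
  }
  if (nrow(x) < n_folds) {
    abort(sprintf("supersection '%s': %d conditions is fewer than %d folds",
                  supersection, nrow(x), n_folds))
  }

  folds <- with_seed(seed, stratified_folds(labels, n_folds))
  scores <- vapply(radius_grid, function(r) {
    fold_f1 <- vapply(seq_len(n_folds), function(k) {
      hold <- folds == k
      if (!any(hold) || all(hold)) return(NA_real_)
      pred <- predict_labels(x[!hold, , drop = FALSE], labels[!hold],
                             x[hold, , drop = FALSE], r)
      weighted_f1(labels[hold], pred)
    }, numeric(1))
    mean(fold_f1, na.rm = TRUE)
  }, numeric(1))
  best <- which(scores == max(scores))[1] # grid sorted: ties -> smallest radius
  structure(
    list(supersection = supersection, species_axes = colnames(x), x = x,
         labels = labels, radius = radius_grid[best],
         cv_radius_grid = radius_grid,
         cv = tibble(radius = radius_grid, mean_f1 = scores),
         selected_score = scores[best], single_label = FALSE),
    class = "ft_classifier")
}

#' @export
print.ft_classifier <- function(x, ...) {
  cat(sprintf(
    "<ft_classifier> %s: %d conditions, %d species axes, %d types\n  radius %.3f (CV weighted F1 %.3f)\n",
    x$supersection, nrow(x$x), length(x$species_axes),
    length(unique(x$labels)), x$radius, x$selected_score))
  invisible(x)
}

#' Fit classifiers for every supersection present in an inventory
#'
#' @inheritParams fit_classifier
#' @return Named list of `ft_classifier` objects (class
#'   `ft_classifier_store`), one per supersection.
#' @export
fit_classifiers <- function(conditions, radius_grid = default_radius_grid(),
                            n_folds = 5, seed = 1L) {
  supersections <- sort(unique(conditions$supersection))
  store <- lapply(supersections, function(ss) {
    fit_classifier(conditions, ss, radius_grid, n_folds, seed)
  })
  structure(setNames(store, supersections), class = "ft_classifier_store")
}

#' @export
print.ft_classifier_store <- function(x, ...) {
  cat(sprintf("<ft_classifier_store> %d supersection(s)\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' Classify a species composition into forest-type probabilities
#'
#' The composition is restricted to the model's species axes (species unseen
#' in training are dropped, with a log message) and renormalized to sum to 1.
#' The probability of forest type `t` is the count of training vectors labeled
#' `t` within the Euclidean radius divided by the count of all training
#' vectors within the radius; with zero neighbors the single nearest
#' training vector's label gets probability 1 (logged fallback).
#'
#' @param model An `ft_classifier`.
#' @param composition Named numeric vector of fractional basal area by species.
#' @return Named numeric vector of probabilities over forest-type codes,
#'   summing to 1, with attribute `fallback` (logical).
#' @export
classify_composition <- function(model, composition) {
  stopifnot(inherits(model, "ft_classifier"))
  if (length(composition) == 0) abort("empty species composition")
  known <- intersect(names(composition), model$species_axes)
  dropped <- setdiff(names(composition), model$species_axes)
  if (length(dropped) > 0) {
    inform(paste("species unseen in training dropped:",
                 paste(dropped, collapse = ", ")), class = "recredit_log")
  }
  comp <- composition[known]
  comp <- comp[comp > 0]
  if (length(comp) == 0 || sum(comp) <= 0) {
    abort("composition empty after restricting to the model's species axes")
  }
  comp <- comp / sum(comp)

  if (isTRUE(model$single_label)) {
    out <- setNames(1, model$labels[1])
    attr(out, "fallback") <- FALSE
    return(out)
  }
  q <- matrix(0, 1, length(model$species_axes),
              dimnames = list(NULL, model$species_axes))
  q[1, names(comp)] <- comp
  d2 <- cross_dist2(q, model$x)[1, ]
  nb <- which(d2 <= model$radius^2 + 1e-12)
  fallback <- length(nb) == 0
  if (fallback) {
    nb <- which.min(d2)
    inform("no training vectors within radius: nearest-neighbor fallback",
           class = "recredit_log")
  }
  tab <- table(model$labels[nb])
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  attr(out, "fallback") <- fallback
  out
}

#' Forest-type probabilities for every assessment area of a project
#'
#' Uses the project's per-assessment-area species composition where reported;
#' when only a project-wide composition exists, the same composition is
#' applied uniformly to every assessment area of the project.
#'
#' @param store An `ft_classifier_store` from [fit_classifiers()].
#' @param project One project record (a single row of a project tibble, or an
#'   equivalent list).
#' @return Tibble with columns `project_id`, `assessment_area`, and `probs`
#'   (list-column of named probability vectors) plus `fallback`.
#' @export
project_forest_types <- function(store, project) {
  ss <- project$supersection[[1]]
  model <- store[[ss]]
  if (is.null(model)) abort(sprintf("no classifier for supersection '%s'", ss))
  areas <- project$areas[[1]]
  species <- project$species[[1]]
  level <- project$species_level[[1]]
  res <- lapply(seq_len(nrow(areas)), function(i) {
    aa <- areas$assessment_area[i]
    comp <- if (identical(level, "per-assessment-area")) {
      if (is.null(species[[aa]])) {
        abort(sprintf("project '%s' has no species data for assessment area '%s'",
                      project$project_id[[1]], aa))
      }
      species[[aa]]
    } else {
      species
    }
    classify_composition(model, comp)
  })
  tibble(project_id = project$project_id[[1]],
         assessment_area = areas$assessment_area,
         probs = res,
         fallback = vapply(res, function(p) isTRUE(attr(p, "fallback")),
                           logical(1)))
}

#' Classify every project in a portfolio
#'
#' @param store An `ft_classifier_store`.
#' @param projects Project tibble.
#' @return Row-bound [project_forest_types()] results for all projects.
#' @export
classify_projects <- function(store, projects) {
  bind_rows(lapply(seq_len(nrow(projects)), function(i) {
    project_forest_types(store, projects[i, ])
  }))
}
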