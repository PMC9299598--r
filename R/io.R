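# Plain-text serialization: inventory conditions as CSV (species fractions as
# a JSON-encoded mapping column), project records as JSON, classifier model
# stores as JSON. Every format carries a schema_version field.

INVENTORY_SCHEMA_VERSION <- 1L
PROJECT_SCHEMA_VERSION <- 1L
MODEL_SCHEMA_VERSION <- 1L

#' Write an inventory condition table to CSV
#'
#' One row per condition; the species mapping is JSON-encoded into a single
#' column so the file stays RFC 4180 CSV.
#'
#' @param inventory Condition tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inventory_csv <- function(inventory, path) {
  flat <- inventory
  flat$species_fractions <- vapply(
    inventory$species_fractions,
    function(f) as.character(jsonlite::toJSON(as.list(f), auto_unbox = TRUE,
                                              digits = NA)),
    character(1))
  flat$schema_version <- INVENTORY_SCHEMA_VERSION
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Read an inventory condition table from CSV
#'
#' @param path File written by [write_inventory_csv()].
#' @return Validated condition tibble.
#' @export
read_inventory_csv <- function(path) {
  flat <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  flat$species_fractions <- lapply(flat$species_fractions, function(s) {
    unlist(jsonlite::fromJSON(s))
  })
  flat$schema_version <- NULL
  validate_inventory(flat)
  flat
}

project_to_record <- function(row) {
  species <- row$species[[1]]
  list(
    project_id = row$project_id, supersection = row$supersection,
    acreage = row$acreage, initial_onsite_carbon = row$initial_onsite_carbon,
    wood_products_project = row$wood_products_project,
    wood_products_baseline = row$wood_products_baseline,
    baseline_avg_density = row$baseline_avg_density,
    secondary_effects = row$secondary_effects,
    confidence_deduction = row$confidence_deduction,
    credits_issued = row$credits_issued,
    species_level = row$species_level,
    areas = lapply(seq_len(nrow(row$areas[[1]])), function(i) {
      as.list(row$areas[[1]][i, ])
    }),
    species = if (identical(row$species_level, "per-assessment-area")) {
      lapply(species, as.list)
    } else {
      as.list(species)
    }
  )
}

#' Write project records to JSON
#'
#' @param projects Project tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_projects_json <- function(projects, path) {
  records <- lapply(seq_len(nrow(projects)), function(i) {
    project_to_record(as.list(projects[i, ]))
  })
  jsonlite::write_json(
    list(schema_version = PROJECT_SCHEMA_VERSION, projects = records),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read project records from JSON
#'
#' @param path File written by [write_projects_json()].
#' @return Project tibble.
#' @export
read_projects_json <- function(path) {
  raw <- jsonlite::read_json(path)
  recs <- raw$projects
  bind_rows(lapply(recs, function(r) {
    areas <- bind_rows(lapply(r$areas, as_tibble))
    species <- if (identical(r$species_level, "per-assessment-area")) {
      lapply(r$species, unlist)
    } else {
      unlist(r$species)
    }
    tibble(
      project_id = r$project_id, supersection = r$supersection,
      acreage = r$acreage, initial_onsite_carbon = r$initial_onsite_carbon,
      wood_products_project = r$wood_products_project,
      wood_products_baseline = r$wood_products_baseline,
      baseline_avg_density = r$baseline_avg_density,
      secondary_effects = r$secondary_effects,
      confidence_deduction = r$confidence_deduction,
      credits_issued = r$credits_issued,
      species_level = r$species_level,
      areas = list(areas), species = list(species))
  }))
}

#' Serialize a classifier model store to JSON
#'
#' Stores, per supersection: species axes, training vectors and labels, the
#' selected radius, the cross-validation report and score.
#'
#' @param store An `ft_classifier_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_store <- function(store, path) {
  models <- lapply(store, function(m) {
    list(supersection = m$supersection, species_axes = as.list(m$species_axes),
         radius = m$radius, cv_radius_grid = m$cv_radius_grid,
         selected_score = m$selected_score, single_label = m$single_label,
         labels = m$labels,
         training = apply(m$x, 1, as.list, simplify = FALSE),
         cv = list(radius = m$cv$radius, mean_f1 = m$cv$mean_f1))
  })
  jsonlite::write_json(list(schema_version = MODEL_SCHEMA_VERSION,
                            models = models),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier model store from JSON
#'
#' @param path File written by [write_model_store()].
#' @return An `ft_classifier_store`.
#' @export
read_model_store <- function(path) {
  raw <- jsonlite::read_json(path)
  store <- lapply(raw$models, function(m) {
    axes <- unlist(m$species_axes)
    x <- do.call(rbind, lapply(m$training, function(r) unlist(r)[axes]))
    colnames(x) <- axes
    structure(
      list(supersection = m$supersection, species_axes = axes, x = x,
           labels = unlist(m$labels), radius = m$radius,
           cv_radius_grid = unlist(m$cv_radius_grid),
           cv = tibble(radius = unlist(m$cv$radius),
                       mean_f1 = unlist(m$cv$mean_f1)),
           selected_score = m$selected_score,
           single_label = isTRUE(m$single_label)),
      class = "ft_classifier")
  })
  structure(setNames(store, vapply(store, `[[`, character(1), "supersection")),
            class = "ft_classifier_store")
}

#' Write common-practice estimates to CSV
#'
#' @param estimates Estimate tibble from [estimate_common_practice()] and
#'   friends.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}
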