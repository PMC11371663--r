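# End-to-end orchestration: one paired-taxon analysis, and the study-level
# aggregation with study-wide multiple-comparison adjustment and the
# Table-style report.

#' Analysis settings for a pair / study run
#'
#' @param R Niche-grid resolution per axis (default 100).
#' @param B Randomization replicates per directional test (default 1000).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param margin Niche-grid range expansion per side (default 0.05).
#' @param availability_floor Support floor as a fraction of `max(e)`.
#' @param max_uncertainty_m Strict coordinate-uncertainty bound in metres;
#'   `NULL` derives half a cell width at the equator from the grid.
#' @param allowed_bases Accepted record-basis values.
#' @param missing_uncertainty Policy for records lacking uncertainty.
#' @param null Randomization null strategy (`"shift"` or `"resample"`).
#' @param hdr_level HDR probability level for the kernel volume.
#' @param variables Climate variables profiled univariately; `NULL` = all.
#' @param run_tests Run the similarity/difference randomization tests
#'   (disable for overlap-only sweeps).
#' @return A list of validated settings.
#' @export
pair_settings <- function(R = 100, B = 1000, alpha = 0.05, margin = 0.05,
                          availability_floor = 1e-6,
                          max_uncertainty_m = NULL,
                          allowed_bases = c("HUMAN_OBSERVATION",
                                            "PRESERVED_SPECIMEN",
                                            "LIVING_SPECIMEN"),
                          missing_uncertainty = c("exclude", "keep"),
                          null = c("shift", "resample"),
                          hdr_level = 0.95, variables = NULL,
                          run_tests = TRUE) {
  missing_uncertainty <- match.arg(missing_uncertainty)
  null <- match.arg(null)
  stopifnot(is_count(R, 10), alpha > 0, alpha < 1,
            hdr_level > 0, hdr_level < 1)
  if (run_tests && !is_count(B, 99)) stop("B must be an integer >= 99")
  list(R = R, B = B, alpha = alpha, margin = margin,
       availability_floor = availability_floor,
       max_uncertainty_m = max_uncertainty_m,
       allowed_bases = allowed_bases,
       missing_uncertainty = missing_uncertainty, null = null,
       hdr_level = hdr_level, variables = variables, run_tests = run_tests)
}

#' Define one extinct/extant taxon pair
#'
#' @param family Family name (bookkeeping only).
#' @param taxon_extinct,taxon_extant Taxon labels matching the occurrence
#'   records' taxon column.
#' @return A `pair_config`.
#' @export
pair_config <- function(family, taxon_extinct, taxon_extant) {
  stopifnot(nzchar(taxon_extinct), nzchar(taxon_extant))
  structure(list(family = family, taxon_extinct = taxon_extinct,
                 taxon_extant = taxon_extant,
                 pair_id = paste(taxon_extinct, "vs", taxon_extant)),
            class = "pair_config")
}

# Filter one taxon's records, downscale to cells, and project into the
# niche space. Returns NULL-bearing skip info when too few cells remain.
prepare_taxon <- function(taxon, records, grid, background, space,
                          settings) {
  rec <- records[records$taxon == taxon, , drop = FALSE]
  maxu <- settings$max_uncertainty_m %||% default_uncertainty_threshold(grid)
  filt <- filter_records(rec, maxu, settings$allowed_bases,
                         settings$missing_uncertainty)
  co <- assign_to_cells(filt, grid, background)
  if (length(co$cells) < 5) {
    return(list(ok = FALSE,
                reason = paste0(taxon, ": only ", length(co$cells),
                                " occupied cells (>= 5 required)"),
                cells = co, filter_drops = attr(filt, "drop_counts")))
  }
  vals <- grid$values[co$cells, , drop = FALSE]
  scores <- predict(space, vals)[, 1:2, drop = FALSE]
  list(ok = TRUE, cells = co, values = vals, scores = scores,
       filter_drops = attr(filt, "drop_counts"))
}

#' Run the full analysis for one taxon pair
#'
#' Sequences filtering, downscaling, projection, occupancy grids,
#' Schoener's D, the two directional randomization tests, the univariate
#' overlap profile, and both niche-volume estimators. Deterministic given
#' `seed`; a taxon with fewer than 5 occupied cells produces a structured
#' skip record rather than an error.
#'
#' @param pair A [pair_config()].
#' @param records Parsed occurrence records for (at least) both taxa.
#' @param grid The `climate_grid`.
#' @param background The `background_set`.
#' @param space The shared `environmental_space`.
#' @param settings A [pair_settings()] list.
#' @param seed Seed for this pair; per-stage seeds are derived from it.
#' @param avail Optional pre-built `availability_density` (rebuilt from
#'   the background scores otherwise).
#' @return A `pair_report`.
#' @export
run_pair <- function(pair, records, grid, background, space,
                     settings = pair_settings(), seed = 1L, avail = NULL) {
  stopifnot(inherits(pair, "pair_config"))
  avail <- avail %||% build_availability_density(
    space$scores[, 1:2, drop = FALSE], R = settings$R,
    margin = settings$margin)
  skip <- function(reason, drops = NULL) {
    structure(list(pair_id = pair$pair_id, family = pair$family,
                   taxon_extinct = pair$taxon_extinct,
                   taxon_extant = pair$taxon_extant,
                   skipped = TRUE, reason = reason, drops = drops,
                   seed = as.integer(seed)),
              class = "pair_report")
  }
  pa <- prepare_taxon(pair$taxon_extinct, records, grid, background, space,
                      settings)
  if (!pa$ok) return(skip(pa$reason, pa$filter_drops))
  pb <- prepare_taxon(pair$taxon_extant, records, grid, background, space,
                      settings)
  if (!pb$ok) return(skip(pb$reason, pb$filter_drops))

  ga <- build_occupancy(pa$scores, avail, settings$availability_floor)
  gb <- build_occupancy(pb$scores, avail, settings$availability_floor)
  d <- schoeners_d(ga, gb)

  tests <- NULL
  if (isTRUE(settings$run_tests)) {
    tests <- list(
      a = similarity_test(ga, gb, B = settings$B,
                          seed = derive_seed(seed, pair$pair_id, "test_a"),
                          randomize = "a", null = settings$null),
      b = similarity_test(ga, gb, B = settings$B,
                          seed = derive_seed(seed, pair$pair_id, "test_b"),
                          randomize = "b", null = settings$null))
  }

  profile <- pairwise_variable_profile(pa$values, pb$values,
                                       settings$variables)
  volumes <- data.frame(
    taxon = c(pair$taxon_extinct, pair$taxon_extant),
    status = c("extinct", "extant"),
    schoener_volume = c(schoener_volume(ga), schoener_volume(gb)),
    hdr_volume = c(
      hdr_volume(pa$scores, avail, level = settings$hdr_level),
      hdr_volume(pb$scores, avail, level = settings$hdr_level)),
    n_occupied_cells = c(ga$n_occ, gb$n_occ),
    stringsAsFactors = FALSE)

  structure(list(pair_id = pair$pair_id, family = pair$family,
                 taxon_extinct = pair$taxon_extinct,
                 taxon_extant = pair$taxon_extant,
                 skipped = FALSE, d = d, tests = tests,
                 variable_overlaps = profile, volumes = volumes,
                 provenance = list(
                   seed = as.integer(seed),
                   settings = settings,
                   n_records = c(a = pa$cells$n_records,
                                 b = pb$cells$n_records),
                   n_cells = c(a = length(pa$cells$cells),
                               b = length(pb$cells$cells)),
                   filter_drops = list(a = pa$filter_drops,
                                       b = pb$filter_drops),
                   cell_drops = list(a = pa$cells$drop_counts,
                                     b = pb$cells$drop_counts))),
            class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  cat("Pair:", x$pair_id, if (!is.null(x$family)) paste0("(", x$family, ")"),
      "\n")
  if (isTRUE(x$skipped)) {
    cat("  skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat("  Schoener's D:", signif(x$d, 3), "\n")
  if (!is.null(x$tests)) {
    cat("  p similarity (a, b):",
        signif(x$tests$a$p_similarity, 4),
        signif(x$tests$b$p_similarity, 4), "\n")
    cat("  p difference (a, b):",
        signif(x$tests$a$p_difference, 4),
        signif(x$tests$b$p_difference, 4), "\n")
  }
  invisible(x)
}

#' Run a full paired-taxon study
#'
#' Runs every pair, applies one multiple-comparison adjustment across all
#' directional similarity tests of the study (and, separately, all
#' difference tests), classifies pairs by the dagger scheme, tallies
#' categories, and compares niche volumes between the extinct and extant
#' groups. Per-pair seeds are derived from the master seed and the pair
#' id, so re-running a single pair reproduces its slice of the full run.
#'
#' @param pairs List of [pair_config()]s (>= 1).
#' @param records Parsed occurrence records for all taxa.
#' @param grid The `climate_grid`.
#' @param background The `background_set`.
#' @param space Optional pre-fitted `environmental_space` (fitted on the
#'   background if `NULL`).
#' @param settings A [pair_settings()] list.
#' @param master_seed Master RNG seed.
#' @param adjust_method Multiple-comparison method (default `"holm"`).
#' @return A `study_report`.
#' @export
run_study <- function(pairs, records, grid, background, space = NULL,
                      settings = pair_settings(), master_seed = 1L,
                      adjust_method = "holm") {
  if (length(pairs) < 1) stop("at least one pair is required")
  space <- space %||% fit_environmental_pca(background)
  avail <- build_availability_density(space$scores[, 1:2, drop = FALSE],
                                      R = settings$R,
                                      margin = settings$margin)
  reports <- lapply(pairs, function(p) {
    run_pair(p, records, grid, background, space, settings,
             seed = derive_seed(master_seed, p$pair_id), avail = avail)
  })
  done <- !vapply(reports, function(r) isTRUE(r$skipped), logical(1))
  if (!any(done)) stop("all pairs were skipped")

  tab <- NULL
  if (isTRUE(settings$run_tests)) {
    p_sim <- unlist(lapply(reports[done], function(r) {
      c(r$tests$a$p_similarity, r$tests$b$p_similarity)
    }))
    p_diff <- unlist(lapply(reports[done], function(r) {
      c(r$tests$a$p_difference, r$tests$b$p_difference)
    }))
    p_sim_adj <- adjust_pvalues(p_sim, adjust_method)
    p_diff_adj <- adjust_pvalues(p_diff, adjust_method)
    rows <- list()
    k <- 0
    for (i in which(done)) {
      r <- reports[[i]]
      cls <- classify_pair(p_sim_adj[2 * k + 1:2], p_diff_adj[2 * k + 1:2],
                           settings$alpha)
      reports[[i]]$classification <- cls
      reports[[i]]$p_adjusted <- list(similarity = p_sim_adj[2 * k + 1:2],
                                      difference = p_diff_adj[2 * k + 1:2])
      rows[[length(rows) + 1]] <- data.frame(
        family = r$family %||% NA_character_, pair = r$pair_id,
        schoeners_d = r$d,
        p_sim_a = r$tests$a$p_similarity, p_sim_b = r$tests$b$p_similarity,
        p_sim_adj_a = p_sim_adj[2 * k + 1],
        p_sim_adj_b = p_sim_adj[2 * k + 2],
        p_diff_adj_a = p_diff_adj[2 * k + 1],
        p_diff_adj_b = p_diff_adj[2 * k + 2],
        similarity = cls$similarity, difference = cls$difference,
        similarity_symbol = cls$similarity_symbol,
        difference_symbol = cls$difference_symbol,
        stringsAsFactors = FALSE)
      k <- k + 1
    }
    tab <- do.call(rbind, rows)
  }

  category_counts <- NULL
  if (!is.null(tab)) {
    similar <- tab$similarity %in% c("similar_one", "similar_both")
    category_counts <- c(similar = sum(similar),
                         non_similar = sum(!similar))
  }

  volume_comparison <- NULL
  if (sum(done) >= 3) {
    vget <- function(col, status) {
      vapply(reports[done], function(r) {
        r$volumes[[col]][r$volumes$status == status]
      }, numeric(1))
    }
    volume_comparison <- list(
      schoener = compare_volume_groups(vget("schoener_volume", "extinct"),
                                       vget("schoener_volume", "extant")),
      hdr = compare_volume_groups(vget("hdr_volume", "extinct"),
                                  vget("hdr_volume", "extant")))
  }

  structure(list(pairs = reports, table = tab,
                 category_counts = category_counts,
                 volume_comparison = volume_comparison,
                 n_pairs = length(reports), n_skipped = sum(!done),
                 provenance = list(master_seed = as.integer(master_seed),
                                   adjust_method = adjust_method,
                                   settings = settings,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "nichelegacy")))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Niche legacy study:", x$n_pairs, "pairs (", x$n_skipped,
      "skipped )\n")
  if (!is.null(x$category_counts)) {
    cat("  similar:", x$category_counts["similar"],
        " non-similar:", x$category_counts["non_similar"], "\n")
  }
  if (!is.null(x$table)) {
    print(x$table[, c("pair", "schoeners_d", "similarity_symbol",
                      "difference_symbol")], row.names = FALSE)
  }
  if (!is.null(x$volume_comparison)) {
    cat("Volume comparison (Schoener):\n")
    print(x$volume_comparison$schoener)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' `report.csv` mirrors the classic overlap table (pair, D, dagger flags);
#' `report.json` carries the full machine-readable report including the
#' null distributions; output is deterministic for a fixed master seed (no
#' timestamps).
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return Invisible character vector of written paths.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(report$table)) {
    csv <- file.path(dir, "report.csv")
    utils::write.csv(report$table, csv, row.names = FALSE,
                     fileEncoding = "UTF-8")
    paths <- c(paths, csv)
  }
  pair_json <- lapply(report$pairs, function(r) {
    if (isTRUE(r$skipped)) {
      list(pair = r$pair_id, skipped = TRUE, reason = r$reason)
    } else {
      list(pair = r$pair_id, family = r$family, schoeners_d = r$d,
           tests = if (!is.null(r$tests)) list(
             a = r$tests$a[c("d_obs", "p_similarity", "p_difference",
                             "B", "seed", "null", "null_d")],
             b = r$tests$b[c("d_obs", "p_similarity", "p_difference",
                             "B", "seed", "null", "null_d")]),
           classification = r$classification,
           p_adjusted = r$p_adjusted,
           volumes = r$volumes,
           variable_overlaps = r$variable_overlaps,
           provenance = r$provenance[c("seed", "n_records", "n_cells")])
    }
  })
  obj <- list(pairs = pair_json,
              category_counts = as.list(report$category_counts),
              volume_comparison = lapply(report$volume_comparison,
                                         unclass),
              provenance = report$provenance)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(obj, json, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(c(paths, json))
}

#' Read a study configuration file
#'
#' YAML or JSON with a `pairs` list (entries: `family`, `taxon_extinct`,
#' `taxon_extant`) and an optional `settings` block passed to
#' [pair_settings()].
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return List with `pairs` (list of [pair_config()]) and `settings`.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (is.null(cfg$pairs) || length(cfg$pairs) == 0) {
    stop("config must define at least one pair")
  }
  pairs <- lapply(cfg$pairs, function(p) {
    pair_config(p$family %||% NA_character_, p$taxon_extinct,
                p$taxon_extant)
  })
  settings <- do.call(pair_settings, cfg$settings %||% list())
  list(pairs = pairs, settings = settings)
}
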