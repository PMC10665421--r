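# End-to-end orchestration: population -> loads -> surrogate mechanics ->
# invariants -> summaries -> correlations, with CSV/JSON export and a run
# manifest for bookkeeping (n_avatars x n_landmarks simulation records).

#' Strain-field summaries for one avatar
#'
#' Builds the avatar's surrogate geometry and mesh, rescales the landmark
#' loads to the avatar's body weight, computes the interfragmentary motion
#' and cell strain field per landmark, and summarizes each invariant per
#' region with the six descriptive statistics.
#'
#' @param avatar one row of the avatar table.
#' @param loads resolved `landmark_loads` table at the reference body
#'   weight.
#' @param config pipeline configuration.
#' @param keep_field if `TRUE`, also return the per-cell fields.
#' @return A list with `summaries` (data.frame: one row per landmark x
#'   region x quantity) and, if requested, `fields` (named list per
#'   landmark).
#' @export
simulate_avatar_strains <- function(avatar, loads, config = default_config(),
                                    keep_field = FALSE) {
  geom <- surrogate_geometry(avatar$tibia_length_mm, config)
  mesh <- build_gap_mesh(geom)
  stiff <- section_properties(geom, config$materials)
  scaled <- scale_loads(loads, avatar, config$loads$gravity_m_s2)
  quantities <- c("hydrostatic", "oct_shear", "max_principal", "j2")
  regions <- c("gap", "callus")
  n_rows <- nrow(scaled) * length(regions) * length(quantities)
  out <- data.frame(
    avatar_id = rep(avatar$id, n_rows),
    landmark = character(n_rows), region = character(n_rows),
    quantity = character(n_rows),
    mean = numeric(n_rows), median = numeric(n_rows), iqr = numeric(n_rows),
    mad = numeric(n_rows), p90 = numeric(n_rows), p95 = numeric(n_rows)
  )
  fields <- if (keep_field) vector("list", nrow(scaled)) else NULL
  k <- 0L
  for (li in seq_len(nrow(scaled))) {
    motion <- gap_kinematics(scaled[li, ], stiff)
    field <- cell_strain_field(motion, mesh, geom$gap_height_mm,
                               config$materials$tissue_nu)
    field <- field_invariants(field)
    if (keep_field) {
      fields[[li]] <- field
      names(fields)[li] <- scaled$landmark[li]
    }
    for (reg in regions) {
      in_reg <- field$region == reg
      for (qt in quantities) {
        k <- k + 1L
        st <- summarize_field(field[[qt]][in_reg])
        out$landmark[k] <- scaled$landmark[li]
        out$region[k] <- reg
        out$quantity[k] <- qt
        out[k, c("mean", "median", "iqr", "mad", "p90", "p95")] <- st
      }
    }
  }
  list(summaries = out, fields = fields)
}

#' Run the full in silico trial pipeline
#'
#' Executes population synthesis, per-avatar stance-phase surrogate
#' simulations at the five landmarks, invariant summaries and the
#' correlation battery. With `out_dir` set, writes `avatars.csv`,
#' `loads.csv` (per-avatar rescaled landmark loads), `strain_summary.csv`,
#' `correlations.csv` and `manifest.json` (UTF-8, '.' decimal separator).
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config pipeline configuration; see [default_config()] and
#'   [read_config()].
#' @param n_avatars override for `config$pipeline$n_avatars`.
#' @param out_dir optional output directory (created if missing).
#' @param export_strain_field avatar ids whose per-cell strain fields are
#'   written to `strain_field.csv` (default none; the full field over all
#'   avatars is large).
#' @param verbose print stage-level progress with record counts.
#' @return Invisibly, a list with `avatars`, `loads`, `summaries`,
#'   `correlations`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), n_avatars = NULL,
                         out_dir = NULL, export_strain_field = integer(0),
                         verbose = FALSE) {
  config <- validate_config(config)
  if (!is.null(n_avatars)) config$pipeline$n_avatars <- as.integer(n_avatars)
  n <- config$pipeline$n_avatars
  say <- function(...) if (verbose) message(sprintf(...))

  avatars <- generate_population(config, n = n, seed = config$seed)
  say("population: %d avatars", nrow(avatars))

  loads <- load_landmark_table(config)
  n_landmarks <- nrow(loads)
  say("loads: %d landmarks at %g N reference", n_landmarks,
      attr(loads, "reference_bodyweight_n"))

  summaries <- vector("list", n)
  scaled_loads <- vector("list", n)
  fields_out <- list()
  for (i in seq_len(n)) {
    keep <- avatars$id[i] %in% export_strain_field
    sim <- simulate_avatar_strains(avatars[i, ], loads, config,
                                   keep_field = keep)
    summaries[[i]] <- sim$summaries
    if (keep) {
      for (lm_id in names(sim$fields)) {
        f <- sim$fields[[lm_id]]
        f <- cbind(avatar_id = avatars$id[i], landmark = lm_id, f)
        fields_out[[length(fields_out) + 1L]] <- f
      }
    }
    sc <- scale_loads(loads, avatars[i, ], config$loads$gravity_m_s2)
    scaled_loads[[i]] <- cbind(avatar_id = avatars$id[i],
                               as.data.frame(sc))
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  scaled_loads <- do.call(rbind, scaled_loads)
  rownames(scaled_loads) <- NULL
  say("mechanics: %d simulation records, %d summary rows",
      n * n_landmarks, nrow(summaries))

  if (n >= 3L) {
    correlations <- correlation_battery(summaries, avatars)
  } else {
    # battery needs >= 3 avatars; tiny runs still produce mechanics output
    correlations <- NULL
  }
  say("correlations: %d battery rows", NROW(correlations))

  manifest <- list(
    package = "gapmech",
    version = as.character(utils::packageVersion("gapmech")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = config$seed,
    config_hash = config_hash(config),
    n_avatars = n,
    landmarks = loads$landmark,
    n_landmarks = n_landmarks,
    simulation_records = n * n_landmarks,
    summary_rows = nrow(summaries),
    correlation_rows = NROW(correlations)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    }
    wcsv(avatars, "avatars.csv")
    wcsv(scaled_loads, "loads.csv")
    wcsv(summaries, "strain_summary.csv")
    if (!is.null(correlations)) wcsv(correlations, "correlations.csv")
    if (length(fields_out) > 0L) {
      wcsv(do.call(rbind, fields_out), "strain_field.csv")
    }
    # manifest last, as the atomic end-of-run marker
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("outputs written to %s", out_dir)
  }

  invisible(list(avatars = avatars, loads = scaled_loads,
                 summaries = summaries, correlations = correlations,
                 manifest = manifest))
}
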