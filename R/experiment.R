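#' Land-use treatment effect sizes
#'
#' Effect sizes used when applying the four factorial land-use treatments to
#' a canopy specification. Mowing truncates the canopy at `mow_cut`
#' (vegetation cut to about 2 cm by default); fertilization raises
#' chlorophyll by `d_chlorophyll` and leaf density by `density_factor`.
#' Provenance (region-of-origin) effects are baseline shifts of leaf-centre
#' height and chlorophyll spread evenly across regions. `zero_effects()`
#' gives the label-blind null design in which no target is predictable.
#'
#' @param mow_cut Cut height in mm, or `NULL` for no truncation.
#' @param d_chlorophyll Additive chlorophyll increase (clamped at 1).
#' @param density_factor Multiplicative leaf-density factor.
#' @param region_height_shift Half-range in mm of between-region height
#'   baseline shifts.
#' @param region_chlorophyll_shift Half-range of between-region chlorophyll
#'   baseline shifts.
#' @return A `treatment_effects` list.
#' @export
treatment_effects <- function(mow_cut = 20, d_chlorophyll = 0.2,
                              density_factor = 1.2,
                              region_height_shift = 30,
                              region_chlorophyll_shift = 0.05) {
  structure(
    list(
      mow_cut = mow_cut, d_chlorophyll = d_chlorophyll,
      density_factor = density_factor,
      region_height_shift = region_height_shift,
      region_chlorophyll_shift = region_chlorophyll_shift
    ),
    class = "treatment_effects"
  )
}

#' @rdname treatment_effects
#' @export
zero_effects <- function() {
  treatment_effects(
    mow_cut = NULL, d_chlorophyll = 0, density_factor = 1,
    region_height_shift = 0, region_chlorophyll_shift = 0
  )
}

#' Factorial land-use treatment codes
#'
#' The four treatment codes combine a mowing and a fertilization factor:
#' `"00"` (baseline: mown once per year), `"0M"` (additional mowing), `"F0"`
#' (fertilized), `"FM"` (both). In the simulation, the mowing factor means
#' the canopy was recently cut, the fertilization factor that chlorophyll
#' and leaf density are raised.
#'
#' @param treatment A vector of codes.
#' @return `treatment_flags()`: a tibble with `treatment`, `mown` (Y/N) and
#'   `fertilized` (Y/N) columns.
#' @export
treatment_flags <- function(treatment) {
  valid <- c("00", "0M", "F0", "FM")
  bad <- setdiff(unique(treatment), valid)
  if (length(bad) > 0) {
    stop("unknown treatment code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    treatment = treatment,
    mown = factor(ifelse(treatment %in% c("0M", "FM"), "Y", "N"), levels = c("N", "Y")),
    fertilized = factor(ifelse(treatment %in% c("F0", "FM"), "Y", "N"), levels = c("N", "Y"))
  )
}

#' Apply a land-use treatment to a canopy specification
#'
#' Deterministically modifies a [canopy_spec()]: the mowing factor installs
#' `height_cut = mow_cut`; the fertilization factor adds `d_chlorophyll`
#' (clamped at 1) and multiplies leaf density by `density_factor`.
#' Treatments compose with any prior modification of the spec.
#'
#' @param spec A [canopy_spec()].
#' @param treatment One of `"00"`, `"0M"`, `"F0"`, `"FM"`.
#' @param effect_sizes A [treatment_effects()].
#' @return The modified `canopy_spec`.
#' @export
apply_treatment <- function(spec, treatment, effect_sizes = treatment_effects()) {
  stopifnot(inherits(spec, "canopy_spec"))
  flags <- treatment_flags(treatment)
  if (flags$mown == "Y" && !is.null(effect_sizes$mow_cut)) {
    spec$height_cut <- effect_sizes$mow_cut
  }
  if (flags$fertilized == "Y") {
    spec$chlorophyll <- min(1, spec$chlorophyll + effect_sizes$d_chlorophyll)
    spec$leaf_density <- spec$leaf_density * effect_sizes$density_factor
  }
  spec
}

#' Generate a simulated common-garden experiment
#'
#' Assigns `n_sods` plots factorially to `n_regions` regions of origin and
#' the land-use treatments, draws per-sod baseline variation around
#' `base_spec` (with region effects as baseline shifts), and builds one
#' canopy specification per sod and scan event. Events up to `pre_events`
#' are pre-treatment; from the next event on, each sod's treatment is
#' applied. Everything is reproducible from `seed`.
#'
#' @param n_sods Number of sods; must divide evenly over
#'   `n_regions x length(treatments)`.
#' @param n_regions Number of regions of origin.
#' @param treatments Treatment codes, see [treatment_flags()].
#' @param n_events Number of scan events.
#' @param pre_events Number of initial pre-treatment events (default 1 when
#'   `n_events > 1`, else 0).
#' @param effect_sizes A [treatment_effects()].
#' @param base_spec The community-level baseline [canopy_spec()].
#' @param sod_height_sd,sod_chlorophyll_sd,sod_density_cv Between-sod
#'   baseline variation (biological replicate noise).
#' @param seed Random seed.
#' @return A `dwcp_experiment`: list with `design` (sod_id, region,
#'   treatment, mown, fertilized), `specs` (nested lists indexed by event then sod), and
#'   per-scan seeds.
#' @export
generate_experiment <- function(n_sods = 60, n_regions = 3,
                                treatments = c("00", "0M", "F0", "FM"),
                                n_events = 2,
                                pre_events = if (n_events > 1) 1L else 0L,
                                effect_sizes = treatment_effects(),
                                base_spec = canopy_spec(),
                                sod_height_sd = 20,
                                sod_chlorophyll_sd = 0.04,
                                sod_density_cv = 0.10,
                                seed = 1) {
  n_cells <- n_regions * length(treatments)
  if (n_sods %% n_cells != 0) {
    stop("inconsistent design: n_sods (", n_sods,
         ") must divide evenly over ", n_cells,
         " region x treatment cells", call. = FALSE)
  }
  stopifnot(n_events >= 1, pre_events >= 0, pre_events < n_events || n_events == pre_events)

  withr::with_seed(seed, {
    reps <- n_sods / n_cells
    design <- tidyr::expand_grid(
      region = factor(paste0("region_", seq_len(n_regions))),
      treatment = treatments,
      rep = seq_len(reps)
    )
    design <- design[sample.int(nrow(design)), c("region", "treatment")]
    design$sod_id <- sprintf("sod_%03d", seq_len(n_sods))
    design <- dplyr::left_join(design, treatment_flags(unique(design$treatment)),
                               by = "treatment")
    design <- design[, c("sod_id", "region", "treatment", "mown", "fertilized")]

    shift <- if (n_regions > 1) seq(-1, 1, length.out = n_regions) else 0
    region_idx <- as.integer(design$region)
    h_shift <- shift[region_idx] * effect_sizes$region_height_shift
    c_shift <- shift[region_idx] * effect_sizes$region_chlorophyll_shift

    base_specs <- vector("list", n_sods)
    for (i in seq_len(n_sods)) {
      s <- base_spec
      s$height_mean <- max(20, s$height_mean + h_shift[i] + stats::rnorm(1, 0, sod_height_sd))
      s$chlorophyll <- min(1, max(0, s$chlorophyll + c_shift[i] +
                                    stats::rnorm(1, 0, sod_chlorophyll_sd)))
      s$leaf_density <- max(1, s$leaf_density * (1 + stats::rnorm(1, 0, sod_density_cv)))
      base_specs[[i]] <- s
    }

    specs <- vector("list", n_events)
    for (e in seq_len(n_events)) {
      specs[[e]] <- vector("list", n_sods)
      for (i in seq_len(n_sods)) {
        s <- base_specs[[i]]
        if (e > pre_events) s <- apply_treatment(s, design$treatment[i], effect_sizes)
        specs[[e]][[i]] <- s
      }
    }
    scan_seeds <- array(
      sample.int(.Machine$integer.max - 2L, n_sods * n_events * 2L),
      dim = c(n_sods, n_events, 2L)
    )
    structure(
      list(
        design = design, specs = specs, scan_seeds = scan_seeds,
        n_events = n_events, pre_events = pre_events,
        effect_sizes = effect_sizes, base_spec = base_spec, seed = seed
      ),
      class = "dwcp_experiment"
    )
  })
}

#' @export
print.dwcp_experiment <- function(x, ...) {
  cat(sprintf(
    "<dwcp_experiment> %d sods x %d events (%d pre-treatment), %d regions, treatments: %s\n",
    nrow(x$design), x$n_events, x$pre_events,
    nlevels(x$design$region), paste(unique(x$design$treatment), collapse = ", ")
  ))
  invisible(x)
}

#' Scan and phenotype a simulated experiment
#'
#' Simulates every (sod, event) scan of a [generate_experiment()] design
#' with the given scanner, runs the phenotyping pipeline
#' (attenuation correction, segmentation, all 14 parameters) on each cloud,
#' and assembles the labelled parameter table. Clouds are processed one at a
#' time and discarded unless `keep_clouds` is set.
#'
#' @param experiment A `dwcp_experiment`.
#' @param scanner A [scanner_model()]. The default uses a 3 mm grid, the
#'   package's standard scale for experiment-sized simulations.
#' @param max_edge Mesh pruning length in mm; defaults to
#'   `max(5, 2.5 * grid_resolution)` so the mesh stays connected at coarse
#'   scan grids.
#' @param keep_clouds Keep the simulated clouds in the result.
#' @return A list: `table` (labelled parameter tibble, one row per sod and
#'   event), `truth` (per-scan ground truth tibble), optionally `clouds`.
#' @export
phenotype_experiment <- function(experiment,
                                 scanner = scanner_model(grid_resolution = 3, xy_jitter = 0.3),
                                 max_edge = max(5, 2.5 * scanner$grid_resolution),
                                 keep_clouds = FALSE) {
  stopifnot(inherits(experiment, "dwcp_experiment"))
  config <- as_scan_config(scanner)
  design <- experiment$design
  n_sods <- nrow(design)
  rows <- vector("list", n_sods * experiment$n_events)
  truth_rows <- vector("list", n_sods * experiment$n_events)
  clouds <- if (keep_clouds) vector("list", n_sods * experiment$n_events) else NULL

  k <- 0L
  for (e in seq_len(experiment$n_events)) {
    for (i in seq_len(n_sods)) {
      k <- k + 1L
      gen <- generate_canopy(experiment$specs[[e]][[i]],
                             seed = experiment$scan_seeds[i, e, 1], config = config)
      sim <- simulate_scan(gen$scene, scanner, seed = experiment$scan_seeds[i, e, 2])
      seg <- sim$cloud %>%
        correct_distance_attenuation(config, exponent = scanner$attenuation_exponent) %>%
        segment_plants()
      par <- compute_all_parameters(seg, config, max_edge = max_edge,
                                    scan_id = paste0(design$sod_id[i], "_e", e))
      par$sod_id <- design$sod_id[i]
      par$scan_event <- e
      rows[[k]] <- par
      truth_rows[[k]] <- tibble::tibble(
        sod_id = design$sod_id[i], scan_event = e,
        n_leaves = sim$truth$n_leaves,
        total_leaf_area = sim$truth$total_leaf_area,
        visible_leaf_area = sim$truth$visible_leaf_area,
        true_mean_tilt = sim$truth$true_mean_tilt,
        true_height_top_decile = sim$truth$true_height_top_decile
      )
      if (keep_clouds) clouds[[k]] <- sim$cloud
    }
  }
  params <- dplyr::bind_rows(rows)
  table <- aggregate_parameters(params, design)
  out <- list(table = table, truth = dplyr::bind_rows(truth_rows))
  if (keep_clouds) out$clouds <- clouds
  out
}
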