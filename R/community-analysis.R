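#' Assemble a labelled parameter table
#'
#' Joins per-scan parameter rows with the sod label table (region,
#' treatment) into the analysis table, one row per `(sod_id, scan_event)`.
#' `mown` and `fertilized` flags are derived from the treatment code; labels
#' supplied in `labels` that contradict the code raise an error, as do
#' duplicate keys. Missing (flagged) parameter values propagate as `NA`.
#'
#' @param params Tibble of parameter rows carrying `sod_id` (and optionally
#'   `scan_event`).
#' @param labels Tibble with `sod_id`, `region`, `treatment`, optionally
#'   `mown`/`fertilized`.
#' @return The joined parameter table.
#' @export
aggregate_parameters <- function(params, labels) {
  stopifnot("sod_id" %in% colnames(params), "sod_id" %in% colnames(labels))
  keys <- if ("scan_event" %in% colnames(params)) {
    paste(params$sod_id, params$scan_event)
  } else {
    params$sod_id
  }
  if (anyDuplicated(keys)) {
    stop("duplicate (sod_id, scan_event) key: ", keys[duplicated(keys)][1], call. = FALSE)
  }
  if (anyDuplicated(labels$sod_id)) {
    stop("duplicate sod_id in labels: ",
         labels$sod_id[duplicated(labels$sod_id)][1], call. = FALSE)
  }
  stopifnot("treatment" %in% colnames(labels))
  derived <- treatment_flags(labels$treatment)
  for (col in c("mown", "fertilized")) {
    if (col %in% colnames(labels)) {
      given <- as.character(labels[[col]])
      if (any(given != as.character(derived[[col]]))) {
        i <- which(given != as.character(derived[[col]]))[1]
        stop("label contradiction for ", labels$sod_id[i], ": treatment ",
             labels$treatment[i], " implies ", col, " = ",
             as.character(derived[[col]])[i], call. = FALSE)
      }
    }
  }
  labels$mown <- derived$mown
  labels$fertilized <- derived$fertilized
  missing_sods <- setdiff(params$sod_id, labels$sod_id)
  if (length(missing_sods) > 0) {
    stop("no labels for sod(s): ", paste(missing_sods, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(params, labels, by = "sod_id")
}

#' Specific leaf area
#'
#' Leaf area divided by leaf dry weight, in mm^2 per mg.
#'
#' @param leaf_area Leaf area in mm^2.
#' @param dry_mass Leaf dry mass in mg (> 0).
#' @return SLA in mm^2/mg.
#' @examples
#' specific_leaf_area(300, 10) # 30
#' @export
specific_leaf_area <- function(leaf_area, dry_mass) {
  if (any(dry_mass <= 0)) stop("dry_mass must be > 0", call. = FALSE)
  leaf_area / dry_mass
}

#' Nitrogen application rate of a fertilizer dose
#'
#' Converts a per-plot fertilizer granulate dose to an annual nitrogen rate
#' per hectare. The default arguments describe the standard grassland
#' fertilization treatment: 10.3 g of a 24%-N granulate applied once per
#' year to a 0.5 x 0.5 m sod, i.e. ~99 kg N per hectare per year.
#'
#' @param mass_g Granulate mass per application in g.
#' @param n_fraction Nitrogen mass fraction of the granulate.
#' @param area_m2 Fertilized plot area in m^2.
#' @param applications_per_year Applications per year.
#' @return Rate in kg N ha^-1 yr^-1.
#' @examples
#' nitrogen_application_rate() # 98.88
#' @export
nitrogen_application_rate <- function(mass_g = 10.3, n_fraction = 0.24,
                                      area_m2 = 0.5 * 0.5,
                                      applications_per_year = 1) {
  stopifnot(mass_g >= 0, n_fraction >= 0, n_fraction <= 1, area_m2 > 0)
  g_n_per_m2 <- mass_g * n_fraction * applications_per_year / area_m2
  g_n_per_m2 * 1e4 / 1e3  # g/m^2 -> kg/ha
}

#' Community-weighted mean traits
#'
#' Abundance-weighted mean of species-level traits per sod:
#' `CWM_t = sum(a_i t_i) / sum(a_i)` over species with a non-missing value
#' of trait `t`; species missing the trait drop out of both sums for that
#' trait. A (sod, trait) combination with no usable species is `NA`, not 0.
#'
#' @param abundance Long tibble with columns `sod_id`, `species`, `cover`
#'   (cover percentages, >= 0).
#' @param traits Tibble with a `species` column and one numeric column per
#'   trait.
#' @return A tibble, one row per sod, one column per trait.
#' @export
community_weighted_mean <- function(abundance, traits) {
  stopifnot(
    all(c("sod_id", "species", "cover") %in% colnames(abundance)),
    "species" %in% colnames(traits)
  )
  if (any(abundance$cover < 0)) stop("covers must be >= 0", call. = FALSE)
  trait_names <- setdiff(colnames(traits), "species")
  abundance %>%
    dplyr::filter(.data$cover > 0) %>%
    dplyr::inner_join(traits, by = "species") %>%
    tidyr::pivot_longer(dplyr::all_of(trait_names),
                        names_to = "trait", values_to = "value") %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$sod_id, .data$trait) %>%
    dplyr::summarise(
      cwm = sum(.data$cover * .data$value) / sum(.data$cover),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "trait", values_from = "cwm") %>%
    dplyr::right_join(tibble::tibble(sod_id = unique(abundance$sod_id)), by = "sod_id") %>%
    # traits with no usable species anywhere still appear, as all-NA columns
    (function(df) {
      for (tn in setdiff(trait_names, colnames(df))) df[[tn]] <- NA_real_
      df
    }) %>%
    dplyr::arrange(.data$sod_id)
}

#' Random-forest classification of sods
#'
#' Trains a random forest assigning sods to a target grouping (region of
#' origin, land-use treatment, mowing Y/N or fertilizer Y/N) from the 14
#' community parameters (or any supplied predictor columns), with the
#' standard settings `mtry = 4` variables per split and `ntree = 10,000`
#' trees. Accuracy comes from the out-of-bag confusion matrix by default
#' (`method = "cv"` gives k-fold cross-validation instead); variable
#' importance is permutation-based by default, and the top five variables
#' are reported (ties broken by name). Rows with missing predictors are
#' dropped and counted.
#'
#' @param table A labelled parameter table (see [aggregate_parameters()]).
#' @param target One of `"region"`, `"treatment"`, `"mown"`, `"fertilized"`,
#'   or any factor column of `table`.
#' @param n_trees,m_try Forest size and variables per split.
#' @param seed Random seed for reproducibility.
#' @param predictors Predictor column names; defaults to the 14 parameters.
#' @param importance `"permutation"` (mean decrease in accuracy) or
#'   `"impurity"` (mean decrease in Gini).
#' @param method `"oob"` or `"cv"`.
#' @param folds Folds for `method = "cv"`.
#' @return A `dwcp_classification` with accuracy, confusion matrix,
#'   importance table, `top_variables` and settings; see also
#'   [tidy.dwcp_classification()] and [glance.dwcp_classification()].
#' @export
classify <- function(table, target = c("region", "treatment", "mown", "fertilized"),
                     n_trees = 10000, m_try = 4, seed = NULL,
                     predictors = NULL,
                     importance = c("permutation", "impurity"),
                     method = c("oob", "cv"), folds = 5) {
  target <- if (is.character(target)) match.arg(target) else target
  importance <- match.arg(importance)
  method <- match.arg(method)
  if (!target %in% colnames(table)) stop("no column '", target, "' in table", call. = FALSE)
  if (is.null(predictors)) predictors <- intersect(parameter_names(), colnames(table))
  if (length(predictors) == 0) stop("no predictor columns found", call. = FALSE)

  y <- droplevels(factor(table[[target]]))
  x <- as.data.frame(table[, predictors])
  complete <- stats::complete.cases(x) & !is.na(y)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  y <- y[complete]
  if (nrow(x) < 10) stop("need at least 10 complete rows, got ", nrow(x), call. = FALSE)
  if (nlevels(droplevels(y)) < 2) stop("target has a single class", call. = FALSE)
  y <- droplevels(y)

  m_try <- min(m_try, ncol(x))
  run <- function() {
    rf <- randomForest::randomForest(
      x = x, y = y, ntree = n_trees, mtry = m_try, importance = TRUE
    )
    if (method == "oob") {
      confusion <- rf$confusion[, levels(y), drop = FALSE]
    } else {
      fold <- sample(rep(seq_len(folds), length.out = nrow(x)))
      pred <- factor(rep(NA_character_, nrow(x)), levels = levels(y))
      for (f in seq_len(folds)) {
        hold <- fold == f
        m <- randomForest::randomForest(x = x[!hold, , drop = FALSE], y = y[!hold],
                                        ntree = n_trees, mtry = m_try)
        pred[hold] <- stats::predict(m, x[hold, , drop = FALSE])
      }
      confusion <- base::table(observed = y, predicted = pred)
    }
    imp_mat <- randomForest::importance(
      rf, type = if (importance == "permutation") 1 else 2
    )
    list(rf = rf, confusion = confusion, importance = imp_mat)
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  confusion <- as.matrix(fit$confusion)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  imp <- tibble::tibble(
    variable = rownames(fit$importance),
    importance = as.numeric(fit$importance[, 1])
  )
  imp <- imp[order(-imp$importance, imp$variable), ]
  structure(
    list(
      target = target,
      accuracy = accuracy,
      confusion = confusion,
      importance = imp,
      top_variables = utils::head(imp$variable, 5),
      n_used = nrow(x),
      n_dropped = n_dropped,
      settings = list(n_trees = n_trees, m_try = m_try, seed = seed,
                      importance = importance, method = method)
    ),
    class = "dwcp_classification"
  )
}

#' @export
print.dwcp_classification <- function(x, ...) {
  cat(sprintf(
    "<dwcp_classification> target: %s | accuracy (%s): %.3f | n = %d (%d dropped)\n",
    x$target, x$settings$method, x$accuracy, x$n_used, x$n_dropped
  ))
  cat("top variables:", paste(x$top_variables, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a sod classification
#'
#' @param x A `dwcp_classification`.
#' @param ... Unused.
#' @return `tidy()`: one row per predictor with its importance score and
#'   rank. `glance()`: a one-row tibble with accuracy and settings.
#' @method tidy dwcp_classification
#' @export
tidy.dwcp_classification <- function(x, ...) {
  dplyr::mutate(x$importance, rank = dplyr::row_number())
}

#' @rdname tidy.dwcp_classification
#' @method glance dwcp_classification
#' @export
glance.dwcp_classification <- function(x, ...) {
  tibble::tibble(
    target = x$target, accuracy = x$accuracy,
    n = x$n_used, n_dropped = x$n_dropped,
    n_classes = nrow(x$confusion),
    n_trees = x$settings$n_trees, m_try = x$settings$m_try,
    method = x$settings$method
  )
}

#' @rdname tidy.dwcp_classification
#' @param object A `dwcp_classification`.
#' @param top_n Number of variables to show.
#' @method autoplot dwcp_classification
#' @export
autoplot.dwcp_classification <- function(object, top_n = 14, ...) {
  df <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$variable, .data$importance)
  )) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::labs(
      x = paste0("importance (", object$settings$importance, ")"),
      y = NULL,
      title = sprintf("Classification to %s: accuracy %.2f",
                      object$target, object$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Per-event classification accuracy
#'
#' Classifies the sods independently at each scan event, mirroring how
#' classification accuracy is tracked over a season of repeated scans.
#' Events whose classification fails (e.g. a single-class target) are
#' reported with `NA` accuracy and the error message; other events continue.
#'
#' @param table A labelled parameter table with a `scan_event` column.
#' @param target Classification target, see [classify()].
#' @param ... Passed to [classify()].
#' @return A tibble: `scan_event`, `target`, `accuracy`, `n_used`, `note`.
#' @export
accuracy_timeseries <- function(table, target, ...) {
  stopifnot("scan_event" %in% colnames(table))
  events <- sort(unique(table$scan_event))
  purrr::map_dfr(events, function(e) {
    sub <- table[table$scan_event == e, , drop = FALSE]
    res <- tryCatch(classify(sub, target = target, ...), error = identity)
    if (inherits(res, "error")) {
      tibble::tibble(scan_event = e, target = target, accuracy = NA_real_,
                     n_used = NA_integer_, note = conditionMessage(res))
    } else {
      tibble::tibble(scan_event = e, target = target, accuracy = res$accuracy,
                     n_used = res$n_used, note = NA_character_)
    }
  })
}

#' Per-parameter group difference tests
#'
#' For each community parameter, tests for differences between the target's
#' groups: a two-sample Welch t-test for binary targets, a one-way ANOVA
#' F-test otherwise. P-values are reported unadjusted. Degenerate cases
#' (fewer than 2 groups with 2+ observations, or constant data) yield `NA`
#' with a note.
#'
#' @param table A labelled parameter table.
#' @param target Grouping column name.
#' @param parameters Parameter columns to test (default: the 14 present).
#' @return A tibble: `parameter`, `test`, `statistic`, `df`, `df2`,
#'   `p_value`, `note`.
#' @export
group_difference_tests <- function(table, target, parameters = NULL) {
  if (!target %in% colnames(table)) stop("no column '", target, "' in table", call. = FALSE)
  if (is.null(parameters)) parameters <- intersect(parameter_names(), colnames(table))
  g <- droplevels(factor(table[[target]]))
  purrr::map_dfr(parameters, function(p) {
    v <- table[[p]]
    ok <- !is.na(v) & !is.na(g)
    vv <- v[ok]; gg <- droplevels(g[ok])
    counts <- tabulate(gg, nbins = nlevels(gg))
    if (nlevels(gg) < 2 || any(counts < 2)) {
      return(tibble::tibble(parameter = p, test = NA_character_,
                            statistic = NA_real_, df = NA_real_, df2 = NA_real_,
                            p_value = NA_real_, note = "degenerate groups"))
    }
    if (nlevels(gg) == 2) {
      res <- tryCatch(stats::t.test(vv ~ gg), error = identity)
      if (inherits(res, "error")) {
        return(tibble::tibble(parameter = p, test = "t", statistic = NA_real_,
                              df = NA_real_, df2 = NA_real_, p_value = NA_real_,
                              note = conditionMessage(res)))
      }
      tibble::tibble(parameter = p, test = "t",
                     statistic = unname(res$statistic),
                     df = unname(res$parameter), df2 = NA_real_,
                     p_value = res$p.value, note = NA_character_)
    } else {
      fit <- summary(stats::aov(vv ~ gg))[[1]]
      tibble::tibble(parameter = p, test = "F",
                     statistic = fit[["F value"]][1],
                     df = fit[["Df"]][1], df2 = fit[["Df"]][2],
                     p_value = fit[["Pr(>F)"]][1], note = NA_character_)
    }
  })
}
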