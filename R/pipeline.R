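#' Run the full delay-activity analysis on simulated data
#'
#' Chains every stage — simulate, baseline-correct, screen channels, fit
#' the subspace, characterize variability, decode — on one target layout
#' and collects every statistic into a single (JSON-serializable) report
#' list. This is the package's one-call entry point; each stage is also
#' exported separately.
#'
#' Decoding adapts to the layout: direction classification with
#' angle-error geometry on ring layouts, distance classification with
#' the spatial-plane ablation on line layouts, per-ring direction
#' classification with arc-length errors on the three-ring layout.
#'
#' @param layout_name `"ring"`, `"rings3"`, or `"lines"` (the horizontal
#'   and vertical line tasks, simulated and fitted together: a single
#'   line leaves one target coordinate constant, which makes the plane
#'   regression degenerate).
#' @param subject `"J"` or `"R"`.
#' @param params a [generator_params()] object.
#' @param n_per_condition trials per target.
#' @param seed integer seed; all stage seeds derive from it and are
#'   recorded in the report.
#' @param var_threshold PCA variance threshold.
#' @param folds cross-validation folds for the classifiers.
#' @param report optional path; when given, the report is written there
#'   as JSON.
#' @return the report, invisibly when `report` is written; a nested list.
#' @export
run_pipeline <- function(layout_name = "rings3", subject = "J",
                         params = generator_params(), n_per_condition = 50,
                         seed = 1, var_threshold = 0.95, folds = 10,
                         report = NULL) {
  layout_name <- match.arg(layout_name, c("rings3", "ring", "lines"))
  if (layout_name == "lines") {
    layouts <- list(make_target_layout("horizontal", subject),
                    make_target_layout("vertical", subject))
    table <- do.call(pool_trials, lapply(seq_along(layouts), function(i)
      simulate_trials(layouts[[i]], params, n_per_condition,
                      seed = seed + (i - 1L) * 1000003L)))
  } else {
    layouts <- list(make_target_layout(layout_name, subject))
    table <- simulate_trials(layouts[[1]], params, n_per_condition,
                             seed = seed)
  }
  table <- subtract_session_baseline(table)
  screen <- screen_channels(table)
  model <- delay_subspace(table, var_threshold = var_threshold)
  states <- project_states(table, model)
  devs <- decompose_deviations(states)

  out <- list(
    config = list(layout = layout_name, subject = subject,
                  n_per_condition = n_per_condition, seed = seed,
                  var_threshold = var_threshold, folds = folds,
                  deviation_scaling = params$deviation_scaling,
                  w_seed = params$w_seed),
    screen = list(kept = sum(screen$kept), n_channels = attr(screen, "n_channels")),
    subspace = list(
      d = model$d,
      cumulative_variance = cumsum(model$ev_fraction)[seq_len(model$d)],
      plane_explained_variance = explained_variance_in_plane(model)),
    variability = list(
      welch_on_vs_off = welch_ttest(abs(devs$on_axis), abs(devs$off_axis)),
      mean_abs_on = mean(abs(devs$on_axis)),
      mean_abs_off = mean(abs(devs$off_axis)),
      neural_kinematic = correlate_neural_kinematic(states)))

  ell <- equal_frequency_ellipses(states)
  out$variability$ellipses <- list(
    scale = ell$scale, coverage = ell$coverage,
    mean_axis_ratio = mean(ell$ellipses$major_len /
                             pmax(ell$ellipses$minor_len, 1e-12)))

  dists <- unique(round_distance(target_distance(table$target_x,
                                                 table$target_y)))
  if (length(dists) >= 2) {
    rel <- relative_deviation_profile(devs, states)
    out$variability$relative_deviation <- list(
      profile = rel$profile, trend = rel$trend)
    spd <- within_distance_speed_test(table, model)
    out$speed <- list(
      significant_distances = attr(spd, "n_significant"),
      n_distances = nrow(spd),
      residual_distance_correlation = residual_distance_correlation(table, model))
  }

  if (layout_name == "ring") {
    res <- crossval_classify(rate_matrix(table), table$condition_id,
                             folds = folds, seed = seed + 1)
    ang <- decode_errors(res, layouts[[1]], "angle")
    out$decoding <- list(direction_accuracy = res$accuracy,
                         direction_sem = res$sem,
                         mean_angle_error_deg = ang$mean * 180 / pi)
  } else if (layout_name == "lines") {
    X2 <- ablate_to_plane(table, model)
    errs <- list(full = numeric(0), plane = numeric(0))
    acc <- c()
    for (lay in layouts) {
      sel <- table$task == lay$name
      sub <- trial_table(as.data.frame(table)[sel, ])
      full <- distance_classification(sub, lay, folds = folds,
                                      seed = seed + 1)
      abl <- distance_classification(sub, lay,
                                     features = X2[sel, , drop = FALSE],
                                     folds = folds, seed = seed + 1)
      errs$full <- c(errs$full, full$errors)
      errs$plane <- c(errs$plane, abl$errors)
      acc <- c(acc, full$accuracy)
    }
    out$decoding <- list(
      distance_accuracy = mean(acc),
      mean_distance_error = mean(errs$full),
      mean_distance_error_plane_only = mean(errs$plane))
  } else {
    per <- per_distance_direction_accuracy(table, layouts[[1]],
                                           folds = folds, seed = seed + 1)
    # near-perfect rings can have zero error variance; report NA then
    ftest <- tryCatch(
      variance_ratio_test(per$arc_errors$r4$errors,
                          per$arc_errors$r12$errors),
      error = function(e) list(p_value = NA_real_))
    out$decoding <- list(
      per_ring = per$summary,
      arc_variance_ratio_p_r4_vs_r12 = ftest$p_value,
      restricted_mean_arc_error = vapply(per$arc_errors, `[[`, numeric(1),
                                         "restricted_mean"))
  }

  if (!is.null(report)) {
    jsonlite::write_json(out, report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
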