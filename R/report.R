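#' Completeness of follow-up by arm
#'
#' Counts participants with complete 12-month service-use records by arm
#' and overall, with the percentage rounded half-up as reported in trial
#' flow tables.
#'
#' @param tab Analysis table (masked).
#' @return Tibble: `group`, `n`, `n_complete`, `pct_complete`.
#' @export
summarise_completeness <- function(tab) {
  complete <- !(is.na(tab$cost_m7) | is.na(tab$cost_m12))
  by_arm <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = as.character(tab$arm),
                                   complete = complete), .data$group),
    n = dplyr::n(), n_complete = sum(.data$complete), .groups = "drop"
  )
  overall <- tibble::tibble(group = "overall", n = nrow(tab),
                            n_complete = sum(complete))
  out <- dplyr::bind_rows(by_arm, overall)
  out$pct_complete <- completeness_pct(out$n_complete, out$n)
  out
}

#' Disaggregated cost summary by group
#'
#' Group means per cost category on a complete-case basis, with adjusted,
#' bootstrapped differences (intervention minus control) and percentile
#' confidence intervals — the shape of a disaggregated cost table.
#'
#' @param breakdown Per-participant category costs from [cost_breakdown()].
#' @param covariates Adjustment covariates present in `breakdown` (empty
#'   for unadjusted differences).
#' @param B Bootstrap replicates for the difference CIs.
#' @param seed Seed for the bootstrap.
#' @return Tibble: `category`, `mean_control`, `mean_intervention`,
#'   `difference`, `conf.low`, `conf.high`, `n_complete`.
#' @export
summarise_costs <- function(breakdown, covariates = character(),
                            B = 500L, seed = 1L) {
  categories <- c("hospital_cost", "community_cost", "other_therapy_cost",
                  "medication_cost", "intervention_cost", "total_nhs_pss",
                  "productivity_cost")
  categories <- intersect(categories, names(breakdown))
  if (any(table(breakdown$arm) == 0)) abort("Both arms must be non-empty.")
  rows <- lapply(categories, function(cat) {
    keep <- complete.cases(breakdown[, c(cat, covariates)])
    dat <- breakdown[keep, , drop = FALSE]
    if (any(table(dat$arm) == 0)) {
      # not estimable on a complete-case basis (e.g. no one in work)
      return(tibble::tibble(category = cat, mean_control = NA_real_,
                            mean_intervention = NA_real_,
                            difference = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_, n_complete = nrow(dat)))
    }
    means <- tapply(dat[[cat]], dat$arm, mean)
    spec <- adjustment_spec(cat, covariates)
    diff <- adjusted_difference(dat, spec)
    cl <- bootstrap_cloud(dat, spec, spec, B = B,
                          seed = derive_seed(seed, match(cat, categories)))
    ci <- unname(quantile(cl$delta_cost, c(0.025, 0.975)))
    tibble::tibble(
      category = cat,
      mean_control = unname(means["control"]),
      mean_intervention = unname(means["intervention"]),
      difference = diff$estimate,
      conf.low = ci[1], conf.high = ci[2],
      n_complete = nrow(dat)
    )
  })
  dplyr::bind_rows(rows)
}

#' Cost-effectiveness plane
#'
#' Scatter of the bootstrap (delta effect, delta cost) pairs with the
#' willingness-to-pay thresholds drawn as lines through the origin.
#'
#' @param result A `cea_result`.
#' @param wtp Thresholds (GBP per effect unit) to draw.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result, wtp = c(20000, 30000)) {
  stopifnot(inherits(result, "cea_result"))
  unit <- if (result$effect == "qaly") "QALYs" else "HRSD points"
  p <- ggplot2::ggplot(result$cloud,
                       ggplot2::aes(x = .data$delta_effect,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(data = tibble::tibble(
      delta_effect = result$delta_effect, delta_cost = result$delta_cost),
      colour = "red", size = 2) +
    ggplot2::labs(x = paste("Incremental effect,", unit),
                  y = "Incremental cost, GBP",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
  for (l in wtp) {
    p <- p + ggplot2::geom_abline(slope = l, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param result A `cea_result`.
#' @return A ggplot object.
#' @export
plot_ceac <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  unit <- if (result$effect == "qaly") "QALY" else "HRSD point"
  ggplot2::ggplot(result$ceac,
                  ggplot2::aes(x = .data$lambda, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = paste0("Willingness to pay, GBP per ", unit),
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cea_result <- function(object, type = c("plane", "ceac"), ...) {
  type <- match.arg(type)
  if (type == "plane") plot_ce_plane(object, ...) else plot_ceac(object)
}

#' Export plane and CEAC data (and figures)
#'
#' Writes `plane.csv` (the bootstrap cloud: exactly the plotted points) and
#' `ceac.csv` (lambda, probability) under `dir`; optionally renders the two
#' figures as PNG. Outputs are deterministic given the result object.
#'
#' @param result A `cea_result`.
#' @param dir Output directory (created if needed).
#' @param figures Also write `plane.png` and `ceac.png`.
#' @return Invisibly, the paths written.
#' @export
export_plots <- function(result, dir, figures = FALSE) {
  stopifnot(inherits(result, "cea_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plane_path <- file.path(dir, "plane.csv")
  ceac_path <- file.path(dir, "ceac.csv")
  utils::write.csv(as.data.frame(result$cloud), plane_path, row.names = FALSE)
  utils::write.csv(as.data.frame(result$ceac), ceac_path, row.names = FALSE)
  paths <- c(plane = plane_path, ceac = ceac_path)
  if (figures) {
    for (type in c("plane", "ceac")) {
      f <- file.path(dir, paste0(type, ".png"))
      ggplot2::ggsave(f, autoplot(result, type), width = 6, height = 5,
                      dpi = 150)
      paths[[paste0(type, "_png")]] <- f
    }
  }
  invisible(paths)
}

#' Run manifest
#'
#' Audit record of one analysis run: a digest of the configuration, the
#' seeds, the package version, digests of any input files, and a timestamp.
#' Two runs with identical manifests (timestamp aside) produce
#' byte-identical numerical outputs.
#'
#' @param config List of analysis settings.
#' @param seed Master seed.
#' @param files Character vector of input file paths to digest.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seed = NA_integer_,
                         files = character()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  structure(
    list(config_hash = unname(tools::md5sum(tmp)),
         seed = seed,
         package_version = as.character(packageVersion("ceatk")),
         file_digests = if (length(files)) tools::md5sum(files) else
           character(),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n  config:", x$config_hash, "\n  seed:", x$seed,
      "\n  package:", x$package_version, "\n  time:", x$timestamp, "\n")
  if (length(x$file_digests)) {
    cat("  inputs:\n")
    for (f in names(x$file_digests)) cat("   ", x$file_digests[[f]], f, "\n")
  }
  invisible(x)
}
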