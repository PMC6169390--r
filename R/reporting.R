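#' Default screen configuration
#'
#' The flat key/value configuration shared by the reporting runners and the
#' command-line interface: the pool layout (`n_targets`, `n_controls`,
#' `guides_per_target`), sequencing `depth`, competition `generations`,
#' `ploidy`, the detection `alpha`, Monte-Carlo `iterations`, and the root
#' `seed`.
#'
#' @return A named list with the default genome-scale yeast design
#'   (4800 targets x 8 guides, 800 controls, depth 100, 26 generations,
#'   haploid, alpha 0.05, 1000 iterations, seed 1).
#' @export
default_config <- function() {
  list(n_targets = 4800L, n_controls = 800L, guides_per_target = 8L,
       depth = 100L, generations = 26L, ploidy = 1L,
       alpha = 0.05, iterations = 1000L, seed = 1L)
}

#' Load a screen configuration from a YAML file
#'
#' Reads a flat key/value YAML file and merges it over [default_config()];
#' unknown keys are rejected, and the merged configuration is validated by
#' constructing the corresponding [screen_design()].
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @param overrides Named list applied after the file (e.g. from command-line
#'   flags).
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("unknown configuration keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  check_count(cfg$iterations, "iterations")
  check_count(cfg$seed, "seed")
  as_screen_design(cfg)  # validates the design fields
  cfg
}

#' Build a screen design from a configuration
#'
#' @param config A configuration list (see [load_config()]).
#' @return A [screen_design()].
#' @export
as_screen_design <- function(config) {
  screen_design(n_targets = config$n_targets,
                n_controls = config$n_controls,
                guides_per_target = config$guides_per_target,
                depth = config$depth,
                generations = config$generations,
                ploidy = config$ploidy)
}

config_comment <- function(config) {
  paste0("# ", paste(sprintf("%s=%s", names(config),
                             vapply(config, format, character(1))),
                     collapse = " "))
}

write_commented_csv <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the full parameterization of a reporting run — configuration
#' snapshot, root seed, package version, timestamp — together with an MD5
#' checksum for every output file, as JSON.
#'
#' @param out_dir Output directory.
#' @param config Configuration list used for the run.
#' @param files Character vector of produced file paths.
#' @param extra Optional named list of additional fields.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, files, extra = list()) {
  manifest <- c(list(
    package = "barseqpower",
    version = as.character(utils::packageVersion("barseqpower")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  ), extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the detection-power map analysis
#'
#' Evaluates [power_grid()] for the configured design over a mutagenesis-rate
#' x selection-coefficient grid and writes a tidy CSV (with a provenance
#' comment line), optionally a heat-map figure, and a run manifest. The
#' default 20 x 20 grid at 1000 iterations runs at desk scale; pass
#' paper-scale grids (101 x 101, 10,000 iterations) explicitly when needed.
#'
#' @param config Configuration list (see [load_config()]).
#' @param out_dir Output directory (created if missing).
#' @param mu_values,s_values Grid values in \[0, 1\].
#' @param plot Write `power_grid.png` (requires a PNG device; default
#'   `FALSE`).
#' @return Invisibly, a list with the `power_grid` object and the written
#'   file paths.
#' @export
run_power_map <- function(config = default_config(), out_dir,
                          mu_values = seq(0, 1, length.out = 20),
                          s_values = seq(0, 1, length.out = 20),
                          plot = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- as_screen_design(config)
  grid <- power_grid(design, mu_values = mu_values, s_values = s_values,
                     iterations = config$iterations, alpha = config$alpha,
                     seed = config$seed)
  csv <- file.path(out_dir, "power_grid.csv")
  write_commented_csv(as.data.frame(grid), csv, config_comment(config))
  files <- csv
  if (plot) {
    png_path <- file.path(out_dir, "power_grid.png")
    ggplot2::ggsave(png_path, plot_power_grid(grid), width = 6, height = 4.5,
                    dpi = 150)
    files <- c(files, png_path)
  }
  manifest <- write_manifest(out_dir, config, files,
                             extra = list(analysis = "power_map"))
  invisible(list(grid = grid, files = files, manifest = manifest))
}

#' Run the gene-recovery analysis
#'
#' Computes [gene_recovery_curve()] for a set of gene fitness effects under
#' two variants of the configured design — haploid at the configured depth
#' and diploid at `diploid_depth_factor` times that depth (a diploid screen
#' needs deeper sequencing because only cells with both alleles edited show
#' the phenotype) — and writes a tidy CSV, optionally a line plot, and a run
#' manifest.
#'
#' @param config Configuration list (see [load_config()]).
#' @param effects Selection coefficients, one per gene (e.g. from
#'   [sample_effects()]).
#' @param out_dir Output directory (created if missing).
#' @param mu_values Mutagenesis-rate grid.
#' @param thresholds Minimal per-gene success rates.
#' @param diploid_depth_factor Depth multiplier for the diploid variant
#'   (default 2; set to `NULL` to skip the diploid variant).
#' @param plot Write `recovery_curves.png` (default `FALSE`).
#' @return Invisibly, a list with the per-variant `recovery_curve` objects,
#'   the tidy data frame and the written file paths.
#' @export
run_recovery_analysis <- function(config = default_config(), effects,
                                  out_dir,
                                  mu_values = seq(0, 1, by = 0.05),
                                  thresholds = c(0.5, 0.8, 0.95),
                                  diploid_depth_factor = 2,
                                  plot = FALSE) {
  if (missing(effects) || length(effects) < 1) {
    stop("`effects` must supply at least one selection coefficient",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- list(haploid = list(ploidy = 1L, depth = config$depth))
  if (!is.null(diploid_depth_factor)) {
    variants$diploid <- list(
      ploidy = 2L, depth = as.integer(config$depth * diploid_depth_factor))
  }
  curves <- list()
  tidy <- NULL
  for (vn in names(variants)) {
    vcfg <- config
    vcfg$ploidy <- variants[[vn]]$ploidy
    vcfg$depth <- variants[[vn]]$depth
    rc <- gene_recovery_curve(as_screen_design(vcfg), effects = effects,
                              mu_values = mu_values,
                              thresholds = thresholds,
                              iterations = config$iterations,
                              alpha = config$alpha, seed = config$seed)
    curves[[vn]] <- rc
    df <- as.data.frame(rc)
    df$variant <- vn
    df$depth <- vcfg$depth
    tidy <- rbind(tidy, df)
  }
  csv <- file.path(out_dir, "recovery_curves.csv")
  write_commented_csv(tidy, csv, config_comment(config))
  files <- csv
  if (plot) {
    png_path <- file.path(out_dir, "recovery_curves.png")
    ggplot2::ggsave(png_path, plot_recovery_tidy(tidy), width = 7,
                    height = 4.5, dpi = 150)
    files <- c(files, png_path)
  }
  manifest <- write_manifest(out_dir, config, files,
                             extra = list(analysis = "gene_recovery",
                                          n_genes = length(effects)))
  invisible(list(curves = curves, tidy = tidy, files = files,
                 manifest = manifest))
}

#' Heat map of a detection-power grid
#'
#' @param grid A [power_grid()] object.
#' @return A ggplot object (mutagenesis rate vs selection coefficient, fill =
#'   detection rate).
#' @export
plot_power_grid <- function(grid) {
  df <- as.data.frame(grid)
  ggplot2::ggplot(df, ggplot2::aes(x = mu, y = s, fill = power)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "detection\nrate") +
    ggplot2::labs(x = "mutagenesis rate (mu)",
                  y = "selection coefficient (s)",
                  title = "LOF detection power") +
    ggplot2::theme_minimal()
}

#' Line plot of gene-recovery curves
#'
#' @param x A [gene_recovery_curve()] object, or the tidy data frame written
#'   by [run_recovery_analysis()].
#' @return A ggplot object (detected gene fraction vs mutagenesis rate, one
#'   line per threshold, facetted by variant when present).
#' @export
plot_recovery_curve <- function(x) {
  if (inherits(x, "recovery_curve")) x <- as.data.frame(x)
  plot_recovery_tidy(x)
}

plot_recovery_tidy <- function(df) {
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mu, y = detected_fraction,
                               colour = factor(threshold))) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(name = "success-rate\nthreshold") +
    ggplot2::labs(x = "mutagenesis rate (mu)",
                  y = "fraction of genes detected",
                  title = "Gene recovery vs mutagenesis rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if ("variant" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~variant)
  }
  p
}
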