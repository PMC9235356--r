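#' Default pipeline configuration
#'
#' Per-stage parameter blocks for the full workflow
#' (simulate -> rescue -> tads -> v4c -> motifs), plus the global seed.
#' Every value can be overridden through a YAML config file
#' ([read_run_config()]) or programmatically.
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(region_length = 1e6, bin_size = 5000,
                    dup_unit_length = 18000, dup_copies = 2L,
                    dup_start = 450000,
                    n_reads = 100000L, decay_alpha = 1.0, insulation = 0.2),
    rescue = list(mode = "fractional", threshold = 0.99, w = 2L,
                  pseudocount = 0.5, min_d = 2L, spline_df = 6,
                  tol = 1e-4, max_iter = 50L),
    tads = list(factor = 5L, window = 40L, k_max = 5L, min_tad = 4L,
                min_silhouette = 0.15),
    v4c = list(viewpoint = "chrS:520000-525000", smooth_window = 3L),
    motifs = list(pwm = NULL, threshold = 8, anchor_window_bins = 2L)
  )
}

# recursively check cfg against the default schema; unknown keys rejected
check_config_keys <- function(cfg, schema, path = "") {
  for (k in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(schema)) stop("unknown config key: ", full)
    if (is.list(schema[[k]]) && !is.null(cfg[[k]])) {
      if (!is.list(cfg[[k]])) stop("config key ", full, " must be a block")
      check_config_keys(cfg[[k]], schema[[k]], full)
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]])) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  check_config_keys(cfg, default_config())
  s <- cfg$simulate
  if (s$insulation <= 0 || s$insulation > 1) {
    stop("config error: simulate.insulation must lie in (0, 1]")
  }
  if (s$decay_alpha <= 0) stop("config error: simulate.decay_alpha must be > 0")
  if (!cfg$rescue$mode %in% c("fractional", "stringent")) {
    stop("config error: rescue.mode must be 'fractional' or 'stringent'")
  }
  invisible(cfg)
}

#' Read and validate a YAML run configuration
#'
#' Values from the file override the defaults; unknown keys are rejected
#' with the offending key named.
#' @param path YAML file with (a subset of) the [default_config()] blocks.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path) %||% list()
  cfg <- merge_config(default_config(), user)
  check_config_keys(user, default_config())
  validate_config(cfg)
  cfg
}

#' Run the full synthetic-region workflow
#'
#' Executes the stages in dependency order — layout + read simulation,
#' multiread rescue, coarse TAD calling, virtual 4C from the configured
#' viewpoint, and motif scanning / anchor classification on the
#' synthesized region sequence — writing every artifact and a manifest
#' (resolved parameters, seed, file list with MD5 checksums) into
#' `out_dir`. Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config configuration list ([default_config()] /
#'   [read_run_config()]); validated before any stage runs.
#' @param out_dir output directory.
#' @param quiet suppress stage log messages (written to stderr).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  config <- validate_config(merge_config(default_config(), config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  s <- config$simulate
  say("simulate", "layout %g bp / %g bp bins, dup %g bp x %d",
      s$region_length, s$bin_size, s$dup_unit_length, s$dup_copies)
  layout <- build_layout(region_length = s$region_length,
                         bin_size = s$bin_size,
                         dup_unit_length = s$dup_unit_length,
                         dup_copies = s$dup_copies,
                         dup_start = s$dup_start)
  sim <- simulate_contacts(layout, n_reads = s$n_reads,
                           decay_alpha = s$decay_alpha,
                           insulation = s$insulation, seed = config$seed)
  fixture_paths <- write_fixture(sim$reads, layout, out_dir)
  truth_path <- file.path(out_dir, "truth_matrix.tsv")
  write_contact_matrix(sim$truth, truth_path)

  r <- config$rescue
  say("rescue", "mode=%s w=%d pseudocount=%g", r$mode, r$w, r$pseudocount)
  res <- rescue_reads(sim$reads, n_bins = layout$n_bins,
                      bin_size = layout$bin_size, mode = r$mode,
                      threshold = r$threshold, w = r$w,
                      pseudocount = r$pseudocount, tol = r$tol,
                      max_iter = r$max_iter, min_d = r$min_d,
                      spline_df = r$spline_df)
  matrix_path <- file.path(out_dir, "rescued_matrix.tsv")
  write_contact_matrix(res$matrix, matrix_path)

  t <- config$tads
  say("tads", "coarsen x%d, window=%d", t$factor, t$window)
  coarse <- coarsen(res$matrix, t$factor)
  seg <- call_tads(coarse, window = t$window, k_max = t$k_max,
                   min_tad = t$min_tad, min_silhouette = t$min_silhouette)
  tad_bed <- file.path(out_dir, "tads.bed")
  tad_report <- file.path(out_dir, "boundary_report.tsv")
  write_tads(seg, bed_path = tad_bed, report_path = tad_report,
             features = layout)

  v <- config$v4c
  say("v4c", "viewpoint %s", v$viewpoint)
  prof <- virtual_4c(res$matrix, v$viewpoint, smooth_window = v$smooth_window)
  v4c_path <- file.path(out_dir, "v4c.bedgraph")
  export_bedgraph(prof, v4c_path)

  m <- config$motifs
  model <- if (is.null(m$pwm)) {
    read_motif(system.file("extdata", "ctcf_motif_synthetic.tsv",
                           package = "dupHiC", mustWork = TRUE),
               threshold = m$threshold)
  } else read_motif(m$pwm, threshold = m$threshold)
  say("motifs", "threshold %g bits", model$threshold)
  seqc <- synth_region_sequence(layout, model, seed = config$seed)
  fasta_path <- file.path(out_dir, "region.fa")
  write_region_fasta(seqc, fasta_path)
  hits <- scan_pwm(seqc, model)
  hits_path <- file.path(out_dir, "motif_hits.tsv")
  write_motif_hits(hits, model, hits_path)
  anchors <- classify_anchor_orientation(
    hits, seg, anchor_window = m$anchor_window_bins * seg$resolution)
  anchors_path <- file.path(out_dir, "anchor_orientation.tsv")
  utils::write.table(anchors, anchors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- c(fixture_paths,
             truth_matrix = truth_path, rescued_matrix = matrix_path,
             tads = tad_bed, boundary_report = tad_report,
             v4c = v4c_path, region_fasta = fasta_path,
             motif_hits = hits_path, anchors = anchors_path)
  manifest <- list(
    seed = config$seed,
    config = config[c("simulate", "rescue", "tads", "v4c",
                      "motifs")],
    stages = c("simulate", "rescue", "tads", "v4c", "motifs"),
    files = as.list(stats::setNames(basename(files), names(files))),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  say("done", "%d artifacts in %s", length(files), out_dir)
  invisible(manifest)
}
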