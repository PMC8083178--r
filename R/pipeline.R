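#' Default run configuration
#'
#' Central place for the pipeline defaults: significance threshold
#' `alpha = 0.01` and profile window of 30 bins each way.
#'
#' @param mode `"regions"` or `"domains"`.
#' @return named list of defaults.
#' @export
default_config <- function(mode = c("regions", "domains")) {
  mode <- match.arg(mode)
  list(mode = mode, chromosome = "chr1", maps = character(),
       resolution = NULL, regions = NULL, domains = NULL, level = 0L,
       alpha = 0.01, window_bins = 30L, test = "hypergeometric",
       min_samples = 50L, formats = "txt", outdir = ".", plot = FALSE,
       title = NULL, ticks = NULL, colors = NULL, units = "bp",
       quiet = FALSE, verbose = FALSE)
}

#' Parse command-line arguments of the `hicsig` CLI
#'
#' First positional argument selects the mode (`regions` or `domains`);
#' `--map` may be repeated (or comma-separated) for replicates in regions
#' mode. Unknown flags raise a usage error.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return a run-configuration list as from [default_config()].
#' @export
parse_cli_args <- function(args) {
  if (length(args) < 1L || !args[1] %in% c("regions", "domains")) {
    stop("usage: hicsig <regions|domains> --map FILE --resolution BP ...",
         call. = FALSE)
  }
  cfg <- default_config(args[1])
  i <- 2L
  need <- function() {
    if (i + 1L > length(args)) {
      stop(sprintf("flag %s needs a value", args[i]), call. = FALSE)
    }
    args[i + 1L]
  }
  while (i <= length(args)) {
    a <- args[i]
    adv <- 2L
    switch(a,
      "--chr" = { cfg$chromosome <- need() },
      "--map" = { cfg$maps <- c(cfg$maps,
                                strsplit(need(), ",", fixed = TRUE)[[1]]) },
      "--resolution" = { cfg$resolution <- as.integer(need()) },
      "--regions" = { cfg$regions <- need() },
      "--domains" = { cfg$domains <- need() },
      "--level" = { cfg$level <- as.integer(need()) },
      "--alpha" = { cfg$alpha <- as.numeric(need()) },
      "--window" = { cfg$window_bins <- as.integer(need()) },
      "--test" = { cfg$test <- need() },
      "--min-samples" = { cfg$min_samples <- as.integer(need()) },
      "--formats" = { cfg$formats <- strsplit(need(), ",",
                                              fixed = TRUE)[[1]] },
      "--outdir" = { cfg$outdir <- need() },
      "--title" = { cfg$title <- need() },
      "--ticks" = { cfg$ticks <- as.integer(need()) },
      "--colors" = { cfg$colors <- strsplit(need(), ",", fixed = TRUE)[[1]] },
      "--units" = { cfg$units <- need() },
      "--plot" = { cfg$plot <- TRUE; adv <- 1L },
      "--quiet" = { cfg$quiet <- TRUE; adv <- 1L },
      "--verbose" = { cfg$verbose <- TRUE; adv <- 1L },
      stop(sprintf("unknown flag: %s", a), call. = FALSE)
    )
    i <- i + adv
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop("--alpha must lie in (0, 1)", call. = FALSE)
  }
  cfg
}

run_log <- function(cfg, msg, level = "INFO") {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  if (!cfg$quiet) message(line)
  log_path <- file.path(cfg$outdir, "run.log")
  if (dir.exists(cfg$outdir)) cat(line, "\n", sep = "", file = log_path,
                                  append = TRUE)
  invisible(line)
}

check_inputs <- function(cfg, need_regions) {
  if (length(cfg$maps) < 1L) stop("no --map supplied", call. = FALSE)
  for (m in cfg$maps) {
    if (!file.exists(m)) stop(sprintf("map file not found: %s", m),
                              call. = FALSE)
  }
  if (is.null(cfg$resolution)) stop("--resolution is required",
                                    call. = FALSE)
  target <- if (need_regions) cfg$regions else cfg$domains
  what <- if (need_regions) "--regions" else "--domains"
  if (is.null(target)) stop(sprintf("%s is required", what), call. = FALSE)
  if (!file.exists(target)) {
    stop(sprintf("%s file not found: %s", what, target), call. = FALSE)
  }
}

#' Run the regions pipeline end to end
#'
#' Loads the replicate maps and the anchors (BED, or enhancer FASTA when
#' the file ends in `.fa`/`.fasta`), calls significant interactions with
#' the all-replicates rule, writes calls in the requested formats plus the
#' consecutive-cluster table, and (optionally) renders a per-anchor profile
#' plot. Plotting never changes the numerical outputs.
#'
#' @param cfg a run configuration list ([default_config()] /
#'   [parse_cli_args()]).
#' @return the [call_set()], invisibly.
#' @export
run_regions <- function(cfg) {
  check_inputs(cfg, need_regions = TRUE)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  run_log(cfg, sprintf("regions mode: chr=%s, alpha=%g, window=%d bins each way",
                       cfg$chromosome, cfg$alpha, cfg$window_bins))
  maps <- lapply(cfg$maps, load_hic_map, resolution = cfg$resolution,
                 chromosome = cfg$chromosome)
  run_log(cfg, sprintf("loaded %d replicate map(s) of %d bins",
                       length(maps), maps[[1]]$n_bins))
  anchors <- if (grepl("\\.(fa|fasta)$", cfg$regions, ignore.case = TRUE)) {
    read_enhancer_fasta(cfg$regions, cfg$resolution)
  } else {
    read_regions_bed(cfg$regions, cfg$resolution)
  }
  if (nrow(anchors) == 0L) stop("no usable anchors in input", call. = FALSE)
  run_log(cfg, sprintf("%d anchor region(s)", nrow(anchors)))
  calls <- call_interactions(maps, anchors, window_bins = cfg$window_bins,
                             alpha = cfg$alpha,
                             min_samples = cfg$min_samples)
  run_log(cfg, sprintf("%d significant call(s) at q <= %g in all replicates",
                       nrow(calls), cfg$alpha))
  for (fmt in cfg$formats) {
    path <- file.path(cfg$outdir, sprintf("calls.%s", fmt))
    write_calls(calls, path, format = fmt)
    run_log(cfg, sprintf("wrote %s", path))
  }
  cl <- cluster_consecutive(calls)
  cl_path <- file.path(cfg$outdir, "clusters.txt")
  utils::write.table(cl, cl_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  run_log(cfg, sprintf("wrote %s (%d cluster(s))", cl_path, nrow(cl)))
  if (cfg$plot) {
    bg <- fit_background(maps[[1]], cfg$window_bins, cfg$min_samples)
    for (a in seq_len(nrow(anchors))) {
      pr <- profile_pvalues(extract_profile(maps[[1]], anchors[a, ],
                                            cfg$window_bins), bg)
      pr$q <- bh_fdr(pr$p)
      base <- file.path(cfg$outdir,
                        sprintf("profile_%s", gsub("[^A-Za-z0-9_.-]", "_",
                                                   pr$anchor_name)))
      render_plot(function() {
        plot_profile(pr, alpha = cfg$alpha,
                     title = cfg$title %||% NULL,
                     ticks = cfg$ticks %||% 5L,
                     colors = cfg$colors %||% c("steelblue", "firebrick"))
      }, base)
      run_log(cfg, sprintf("wrote %s.{png,svg}", base))
    }
  }
  invisible(calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the domains pipeline end to end
#'
#' Loads one map and the domain borders at the requested hierarchy level,
#' scores every domain pair under the chosen null, writes the p-value,
#' q-value and significant-pairs tables, and optionally renders the
#' triangular map plot.
#'
#' @param cfg a run configuration list.
#' @return the `domain_call_set`, invisibly.
#' @export
run_domains <- function(cfg) {
  check_inputs(cfg, need_regions = FALSE)
  if (length(cfg$maps) != 1L) {
    stop("domains mode takes exactly one --map", call. = FALSE)
  }
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  run_log(cfg, sprintf("domains mode: chr=%s, test=%s, alpha=%g, level=%d",
                       cfg$chromosome, cfg$test, cfg$alpha, cfg$level))
  map <- load_hic_map(cfg$maps[1], resolution = cfg$resolution,
                      chromosome = cfg$chromosome)
  domains <- read_domains(cfg$domains, cfg$resolution, level = cfg$level,
                          units = cfg$units)
  run_log(cfg, sprintf("%d domain(s) at level %d", nrow(domains),
                       cfg$level))
  calls <- call_domain_interactions(map, domains, test = cfg$test,
                                    alpha = cfg$alpha)
  run_log(cfg, sprintf("%d significant pair(s) at q <= %g",
                       sum(calls$significant), cfg$alpha))
  files <- write_domain_calls(calls, cfg$outdir)
  for (f in files) run_log(cfg, sprintf("wrote %s", f))
  if (cfg$plot) {
    base <- file.path(cfg$outdir, "domain_map")
    render_plot(function() {
      plot_domain_map(map, calls,
                      title = cfg$title %||% "domain interactions",
                      ticks = cfg$ticks %||% 10L,
                      colors = cfg$colors %||% c("white", "firebrick"))
    }, base)
    run_log(cfg, sprintf("wrote %s.{png,svg}", base))
  }
  invisible(calls)
}

#' CLI entry point
#'
#' Parses arguments, dispatches to [run_regions()] or [run_domains()], and
#' converts errors into a message on stderr plus a non-zero exit status.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success).
#' @export
main_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  tryCatch({
    cfg <- parse_cli_args(args)
    if (cfg$mode == "regions") run_regions(cfg) else run_domains(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
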