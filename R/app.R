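#' Generate the synthetic benchmark fixture set
#'
#' Writes pattern files for the synthetic benchmark: patterns of 10 spheres
#' of radius 5 in a spherical domain of radius 30 (all lengths in voxel
#' units), simulated under the completely random model, border attraction
#' (`mu = 5`, `sigma = 5`) and border repulsion (`mu = 15`, `sigma = 5`),
#' `n_patterns` of each, as CSV + JSON sidecars under one sub-directory per
#' model, plus a provenance manifest. Optionally each pattern is also
#' rasterized to TIFF mask/label stacks.
#'
#' @param dir output directory (created if needed).
#' @param n_patterns patterns per model (default 100).
#' @param seed integer seed; the same seed reproduces identical files.
#' @param with_masks also write rasterized TIFF stacks (voxel size 1).
#' @param radius,n_objects,object_radius benchmark geometry overrides.
#' @return invisibly, a manifest list (also written as `manifest.json`).
#' @export
generate_fixtures <- function(dir, n_patterns = 100L, seed = 1L,
                              with_masks = FALSE, radius = 30,
                              n_objects = 10L, object_radius = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  domain <- domain_sphere(radius)
  radii <- rep(object_radius, n_objects)
  specs <- list(
    csr = model_spec("csr", radii),
    border_attraction = model_spec("border_attraction", radii,
                                   mu = 5, sigma = 5),
    border_repulsion = model_spec("border_repulsion", radii,
                                  mu = 15, sigma = 5))
  files <- list()
  for (m in names(specs)) {
    sub <- file.path(dir, m)
    dir.create(sub, showWarnings = FALSE)
    for (k in seq_len(n_patterns)) {
      pat <- simulate_model(domain, specs[[m]])
      pat$metadata <- list(model = m, index = k)
      f <- file.path(sub, sprintf("pattern_%03d.csv", k))
      write_pattern(pat, f)
      if (with_masks) {
        ras <- rasterize_pattern(pat, c(1, 1, 1))
        write_mask_tiff(ras$nucleus,
                        file.path(sub, sprintf("pattern_%03d_mask.tif", k)))
        write_labels_tiff(ras$labels,
                          file.path(sub, sprintf("pattern_%03d_labels.tif", k)))
      }
      files[[m]] <- c(files[[m]], basename(f))
    }
  }
  manifest <- list(sdi3d_version = as.character(utils::packageVersion("sdi3d")),
                   seed = seed, n_patterns = n_patterns,
                   domain = list(kind = "sphere", radius = radius),
                   n_objects = n_objects, object_radius = object_radius,
                   models = list(csr = list(),
                                 border_attraction = list(mu = 5, sigma = 5),
                                 border_repulsion = list(mu = 15, sigma = 5)),
                   files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the full SDI analysis over a collection of patterns
#'
#' For every requested model and pattern, runs [sdi_test()]; aggregates the
#' per-descriptor SDI distributions into population KS uniformity tests and
#' compares observed and predicted mean distances ([compare_mean_distances()]).
#'
#' @param patterns list of [object_pattern]s, or a directory of pattern CSVs.
#' @param models character vector of model ids (border-biased models take
#'   their `mu`/`sigma` from `...`).
#' @param descriptors descriptor subset.
#' @param n_sim1,n_sim2,L as in [sdi_test()].
#' @param seed integer seed (mandatory for a reproducible report).
#' @param out_dir optional directory to write `sdi_<model>.csv` (per-pattern
#'   SDIs), `uniformity.csv` and `mean_distances.csv`.
#' @param ... passed to [condition_spec()].
#' @return a report list with elements `sdi` (per model, data frame of
#'   per-pattern SDIs), `uniformity` (data frame: model, descriptor, n, D,
#'   p) and `distances` (data frame of matched Wilcoxon comparisons).
#' @export
run_full_analysis <- function(patterns, models = "csr",
                              descriptors = c("F", "G", "H", "B", "C", "Z"),
                              n_sim1 = 99L, n_sim2 = 99L, L = 10000L,
                              seed = 1L, out_dir = NULL, ...) {
  if (is.character(patterns)) {
    fs <- list.files(patterns, pattern = "\\.csv$", full.names = TRUE)
    fs <- fs[!grepl("(morphology|manifest)", fs)]
    if (!length(fs)) stop("no pattern CSV files found in ", patterns)
    patterns <- lapply(sort(fs), read_pattern)
  }
  stopifnot(length(patterns) >= 1)
  set.seed(seed)
  sdi_tabs <- list()
  unif <- dists <- NULL
  for (m in models) {
    tab <- NULL
    for (k in seq_along(patterns)) {
      fit <- sdi_test(patterns[[k]], m, descriptors, n_sim1 = n_sim1,
                      n_sim2 = n_sim2, L = L, ...)
      tab <- rbind(tab, cbind(pattern = k, fit$results))
    }
    sdi_tabs[[m]] <- tab
    for (d in descriptors) {
      sdis <- tab$sdi[tab$descriptor == d]
      ut <- test_uniformity(sdis)
      unif <- rbind(unif, data.frame(model = m, descriptor = d, n = ut$n,
                                     D = ut$D, p.value = ut$p.value))
    }
    if (length(patterns) >= 6) {
      for (w in c("nearest", "pair", "farthest")) {
        cm <- compare_mean_distances(patterns, m, w,
                                     n_sim_per_pattern = 19L, ...)
        dists <- rbind(dists, data.frame(
          model = m, which = w, mean_observed = mean(cm$observed),
          mean_predicted = mean(cm$predicted), p.value = cm$p.value))
      }
    }
  }
  report <- list(sdi = sdi_tabs, uniformity = unif, distances = dists,
                 config = list(sdi3d_version =
                                 as.character(utils::packageVersion("sdi3d")),
                               models = models, descriptors = descriptors,
                               n_sim1 = n_sim1, n_sim2 = n_sim2, L = L,
                               seed = seed, n_patterns = length(patterns)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(sdi_tabs))
      utils::write.csv(sdi_tabs[[m]],
                       file.path(out_dir, paste0("sdi_", m, ".csv")),
                       row.names = FALSE)
    utils::write.csv(unif, file.path(out_dir, "uniformity.csv"),
                     row.names = FALSE)
    if (!is.null(dists))
      utils::write.csv(dists, file.path(out_dir, "mean_distances.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report$config, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

## ---- command line -------------------------------------------------------

.cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]
        i <- i + 2L
      } else {
        out[[key]] <- TRUE
        i <- i + 1L
      }
    } else i <- i + 1L
  }
  out
}

.cli_domain <- function(s) {
  if (grepl("^sphere:", s)) domain_sphere(as.numeric(sub("^sphere:", "", s)))
  else if (grepl("\\.ply$", s)) read_ply(s)
  else stop("unsupported --domain (use sphere:R or a .ply file)")
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/sdi3d.R` script. Subcommands: `fixtures`, `simulate`,
#' `extract`, `describe`, `sdi`, `population-test`, `analyze`. Run with no
#' arguments for usage. Returns an exit status (0 ok, 1 user error).
#'
#' @param args character vector of command-line arguments.
#' @export
sdi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sdi3d.R <subcommand> [--flag value ...]",
    "  fixtures        --out DIR [--n 100] [--seed 1] [--with-masks]",
    "  simulate        --model csr|orbital|max_repulsion|orbital_max_repulsion|border_attraction|border_repulsion",
    "                  --domain sphere:R|file.ply --radii r1,r2,... --out DIR",
    "                  [--n 1] [--seed 1] [--orbits d1,...] [--mu M --sigma S]",
    "  extract         --mask m.tif --labels l.tif --spacing sx,sy,sz --out stem",
    "  describe        --pattern p.csv --out f.csv [--L 10000] [--seed 1]",
    "  sdi             --pattern p.csv --model M --out f.json [--descriptors F,G,H,B,C,Z]",
    "                  [--nsim 99] [--L 10000] [--seed 1] [--mu M --sigma S]",
    "  population-test --in DIR --out f.csv",
    "  analyze         --in DIR --model M[,M2] --out DIR [--nsim 99] [--L 10000] [--seed 1]",
    sep = "\n")
  if (length(args) == 0) { message(usage); return(1L) }
  sub <- args[1]
  opt <- .cli_args(args[-1])
  num <- function(key, default = NULL) {
    v <- opt[[key]]
    if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1]])
  }
  status <- tryCatch({
    switch(sub,
      fixtures = {
        generate_fixtures(opt$out, n_patterns = num("n", 100),
                          seed = num("seed", 1),
                          with_masks = isTRUE(opt[["with-masks"]]))
        0L
      },
      simulate = {
        set.seed(num("seed", 1))
        domain <- .cli_domain(opt$domain)
        spec <- model_spec(opt$model, radii = num("radii"),
                           orbits = num("orbits"),
                           mu = num("mu"), sigma = num("sigma"))
        dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
        n <- num("n", 1)
        for (k in seq_len(n))
          write_pattern(simulate_model(domain, spec),
                        file.path(opt$out, sprintf("pattern_%03d.csv", k)))
        jsonlite::write_json(
          list(model = opt$model, radii = num("radii"),
               orbits = num("orbits"), mu = num("mu"), sigma = num("sigma"),
               n = n, seed = num("seed", 1)),
          file.path(opt$out, "manifest.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        0L
      },
      extract = {
        res <- extract_pattern(read_mask_tiff(opt$mask),
                               read_labels_tiff(opt$labels),
                               num("spacing"))
        write_pattern(res$pattern, paste0(opt$out, ".csv"))
        utils::write.csv(res$morphology$objects,
                         paste0(opt$out, "_morphology.csv"),
                         row.names = FALSE)
        0L
      },
      describe = {
        pat <- read_pattern(opt$pattern)
        pos <- eval_positions(pat$domain, num("L", 10000),
                              seed = num("seed", 1))
        cdfs <- estimate_descriptors(pat, positions = pos)
        tab <- do.call(rbind, lapply(cdfs, function(f)
          data.frame(descriptor = f$id, x = f$x, cdf = f$cum)))
        utils::write.csv(tab, opt$out, row.names = FALSE)
        0L
      },
      sdi = {
        pat <- read_pattern(opt$pattern)
        nd <- if (is.null(opt$descriptors)) c("F", "G", "H", "B", "C", "Z")
        else strsplit(opt$descriptors, ",")[[1]]
        fit <- sdi_test(pat, opt$model, nd, n_sim1 = num("nsim", 99),
                        n_sim2 = num("nsim", 99), L = num("L", 10000),
                        seed = num("seed", 1), mu = num("mu"),
                        sigma = num("sigma"))
        jsonlite::write_json(
          list(model = opt$model, results = fit$results,
               n_sim1 = fit$n_sim1, n_sim2 = fit$n_sim2,
               seed = num("seed", 1)),
          opt$out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
          dataframe = "rows")
        0L
      },
      `population-test` = {
        fs <- list.files(opt[["in"]], pattern = "\\.json$", full.names = TRUE)
        fs <- fs[!grepl("manifest", fs)]
        recs <- lapply(fs, jsonlite::read_json)
        tab <- NULL
        for (r in recs) for (row in r$results)
          tab <- rbind(tab, data.frame(model = r$model,
                                       descriptor = row$descriptor,
                                       sdi = row$sdi))
        out <- NULL
        for (m in unique(tab$model)) for (d in unique(tab$descriptor)) {
          s <- tab$sdi[tab$model == m & tab$descriptor == d]
          ut <- test_uniformity(s)
          out <- rbind(out, data.frame(descriptor = d, model = m, n = ut$n,
                                       D = ut$D, p.value = ut$p.value))
        }
        utils::write.csv(out, opt$out, row.names = FALSE)
        0L
      },
      analyze = {
        run_full_analysis(opt[["in"]],
                          models = strsplit(opt$model, ",")[[1]],
                          n_sim1 = num("nsim", 99), n_sim2 = num("nsim", 99),
                          L = num("L", 10000), seed = num("seed", 1),
                          out_dir = opt$out, mu = num("mu"),
                          sigma = num("sigma"))
        0L
      },
      { message(usage); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  status
}
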