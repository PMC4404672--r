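#' Pipeline configuration
#'
#' Declares an end-to-end run: simulate a cohort (or read one), filter
#' sites, run the heterozygosity-ratio scan, pairwise F_ST, haplotype
#' sharing, the QTL/selection overlap test, significance thresholds and
#' color phenotyping. One top-level seed drives every stochastic stage
#' through fixed per-stage offsets.
#'
#' @param out_dir output directory (created if absent).
#' @param seed top-level integer seed.
#' @param sim a [simConfig()] (its own seed is overridden by the derived
#'   stage seed), or \code{NULL} to read genotypes from \code{inputs}.
#' @param inputs when \code{sim} is NULL: list with \code{genotypes}
#'   (dosage TSV), \code{pop_labels}, \code{map} paths.
#' @param stages character vector of stages to run, in any order; executed
#'   in dependency order. Subset of \code{c("simulate", "filter",
#'   "hetscan", "fst", "hapshare", "overlap", "thresholds", "color")}.
#' @param params named list of stage knobs; recognised entries (defaults):
#'   \code{max_missing_rate} (0.5), \code{min_maf} (0.02),
#'   \code{wild_pop} ("wild"), \code{window_sites} (500),
#'   \code{top_fraction} (0.05), \code{overlap_top_fraction} (0.01),
#'   \code{bin_cM} (30), \code{n_qtl} (20),
#'   \code{fraction_overlapping_sweeps} (0.5), \code{r2_min} (0.6),
#'   \code{n_snps} (100), \code{alpha} (0.05), \code{n_color_genotypes}
#'   (24), \code{color_noise_sd} (5).
#' @return config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir, seed = 42L, sim = simConfig(),
                           inputs = NULL,
                           stages = c("simulate", "filter", "hetscan",
                                      "fst", "hapshare", "overlap",
                                      "thresholds", "color"),
                           params = list()) {
  all_stages <- c("simulate", "filter", "hetscan", "fst", "hapshare",
                  "overlap", "thresholds", "color")
  stopifnot(all(stages %in% all_stages))
  if (is.null(sim) && "simulate" %in% stages)
    stop("stage 'simulate' requires a simConfig")
  if (is.null(sim) && !"simulate" %in% stages && length(stages)) {
    need <- c("genotypes", "pop_labels", "map")
    if (!all(need %in% names(inputs)) ||
        !all(file.exists(unlist(inputs[need]))))
      stop("without simulation, inputs must name existing genotypes, ",
           "pop_labels and map files")
  }
  defaults <- list(max_missing_rate = 0.5, min_maf = 0.02,
                   wild_pop = "wild", window_sites = 500L,
                   top_fraction = 0.05, overlap_top_fraction = 0.01,
                   bin_cM = 30, n_qtl = 20L,
                   fraction_overlapping_sweeps = 0.5, r2_min = 0.6,
                   n_snps = 100L, alpha = 0.05, n_color_genotypes = 24L,
                   color_noise_sd = 5)
  params <- utils::modifyList(defaults, params)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 inputs = inputs, stages = stages, params = params),
            class = "pipelineConfig")
}

.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, overlap = 211L, color = 307L)
  (seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes one output file
#' per stage under \code{config$out_dir}, and finishes with a
#' \code{manifest.json} recording the package version, seed, parameters
#' and the md5 checksum of every input and output. A rerun with the same
#' config and seed reproduces byte-identical stage outputs. A stage
#' failure halts the run naming the stage.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  on_stage <- function(stage, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", stage, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  outputs <- character(0)
  out <- function(f) file.path(config$out_dir, f)
  gm <- NULL; map <- NULL; truth <- NULL; signatures <- NULL; scan <- NULL

  if ("simulate" %in% config$stages) {
    sim <- on_stage("simulate", {
      cfg <- config$sim
      cfg$seed <- .stage_seed(config$seed, "simulate")
      simulateCohort(cfg)
    })
    gm <- sim$genotypes; map <- sim$map; truth <- sim$truth
    writeGenotypes(gm, out("genotypes.tsv"), "dosage")
    writePopulationLabels(populations(gm), out("populations.tsv"))
    writeGeneticMap(map, out("map.tsv"))
    outputs <- c(outputs, "genotypes.tsv", "populations.tsv", "map.tsv")
  } else if (length(setdiff(config$stages, c("thresholds", "color")))) {
    gm <- on_stage("load", readGenotypes(config$inputs$genotypes, "dosage",
                                         config$inputs$pop_labels))
    map <- readGeneticMap(config$inputs$map)
  }

  if ("filter" %in% config$stages)
    gm <- on_stage("filter",
                   filterSites(gm, p$max_missing_rate, p$min_maf))

  cult_pops <- if (!is.null(gm))
    setdiff(unique(populations(gm)), p$wild_pop)

  if ("hetscan" %in% config$stages) {
    res <- on_stage("hetscan", {
      sc <- hetRatioScan(gm, p$wild_pop, cult_pops, p$window_sites)
      topPercentileRegions(sc, p$top_fraction)
    })
    scan <- res$scan
    writeScanTsv(scan, out("scan.tsv"))
    writeBed(res$regions, out("signatures.bed"))
    outputs <- c(outputs, "scan.tsv", "signatures.bed")
  }

  if ("fst" %in% config$stages) {
    fm <- on_stage("fst", fstMatrix(gm))
    utils::write.table(round(fm, 6), out("fst.tsv"), sep = "\t",
                       quote = FALSE)
    outputs <- c(outputs, "fst.tsv")
  }

  if ("hapshare" %in% config$stages) {
    tab <- on_stage("hapshare", {
      si <- siteInfo(gm)
      reg <- if (!is.null(truth) && length(truth$sweeps)) {
        sw <- truth$sweeps[[1L]]
        IntervalSet(data.frame(chrom = sw$chrom, start = sw$start_bp,
                               end = sw$end_bp, trait = "hapshare"), "bp")
      } else {
        ch <- si$chrom[1L]
        IntervalSet(data.frame(chrom = ch, start = min(si$pos[si$chrom == ch]),
                               end = max(si$pos[si$chrom == ch]),
                               trait = "hapshare"), "bp")
      }
      sites <- selectRegionSnps(gm, reg, p$n_snps)
      sharingMatrix(gm, sites, unique(populations(gm)))
    })
    utils::write.table(tab, out("hapshare.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, "hapshare.tsv")
  }

  if ("overlap" %in% config$stages) {
    res <- on_stage("overlap", {
      bn <- makeBins(map, p$bin_cM)
      sel <- if (!is.null(scan))
        topPercentileRegions(scan, p$overlap_top_fraction)$regions
      else signatures
      if (is.null(sel)) stop("overlap needs the hetscan stage")
      qtl <- if (!is.null(config$inputs$qtl))
        readIntervals(config$inputs$qtl, "bp")
      else simulateIntervals(truth, p$n_qtl,
                             p$fraction_overlapping_sweeps,
                             seed = .stage_seed(config$seed, "overlap"))
      cnt <- countOverlap(bn, sel, qtl, map)
      data.frame(n = cnt@n, l = cnt@l, s = cnt@s, m = cnt@m,
                 p_value = hypergeomOverlapP(cnt))
    })
    utils::write.table(res, out("overlap.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, "overlap.tsv")
  }

  if ("thresholds" %in% config$stages) {
    res <- on_stage("thresholds", {
      n_tests <- if (!is.null(gm)) nSites(gm) else NA_integer_
      # LD is population-specific: estimate the extent within the largest
      # population rather than across the pooled, structured panel
      ld <- if (!is.null(gm)) {
        pops <- populations(gm)
        big <- names(sort(table(pops), decreasing = TRUE))[1L]
        ldDecayExtent(gm[, names(pops)[pops == big]])$extent_bp
      } else NA_real_
      genome <- if (!is.null(config$sim))
        config$sim$n_chromosomes * config$sim$chrom_length_bp
      else if (!is.null(gm)) {
        si <- siteInfo(gm)
        sum(tapply(si$pos, si$chrom, max))
      } else NA_real_
      data.frame(alpha = p$alpha, n_tests = n_tests,
                 bonferroni = if (is.na(n_tests)) NA
                              else bonferroni(p$alpha, n_tests),
                 genome_bp = genome, ld_extent_bp = ld,
                 ld_adjusted = if (is.na(ld) || ld == 0) NA
                               else ldAdjustedThreshold(p$alpha, genome, ld))
    })
    utils::write.table(res, out("thresholds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "thresholds.tsv")
  }

  if ("color" %in% config$stages) {
    res <- on_stage("color", {
      sim <- simulateSeedColors(p$n_color_genotypes,
                                noise_sd = p$color_noise_sd,
                                seed = .stage_seed(config$seed, "color"))
      tab <- colorPhenotypeTable(sim$seeds)
      tab$L <- round(tab$L, 4); tab$a <- round(tab$a, 4)
      tab$b <- round(tab$b, 4)
      tab
    })
    utils::write.table(res, out("colors.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, "colors.tsv")
  }

  input_files <- unlist(config$inputs)
  in_md5 <- if (length(input_files)) {
    h <- tools::md5sum(input_files)
    names(h) <- basename(input_files)
    as.list(h)
  } else list()
  out_md5 <- tools::md5sum(file.path(config$out_dir, outputs))
  names(out_md5) <- outputs
  manifest <- list(
    package = "domescan",
    version = as.character(utils::packageVersion("domescan")),
    seed = config$seed, stages = config$stages, params = p,
    inputs = in_md5, outputs = as.list(out_md5))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
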