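#' Run the full dispersal / gene-flow pipeline from a configuration
#'
#' Executes the stages in order — site/sample filtering, clone detection and
#' removal, linkage pruning, isolation-by-distance regression, density and
#' sigma estimation, diversity, LD-Ne, demographic parameter conversion — on
#' whatever inputs the configuration provides; stages whose inputs are absent
#' are skipped with a notice. Writes per-stage CSV/JSON outputs plus a
#' reproducibility manifest (package version, parameters, seed, input
#' checksums) to the output directory.
#'
#' The configuration is an R list or a path to a JSON file with (all
#' optional unless noted):
#' \describe{
#'   \item{vcf}{SNP VCF path (required for genotype stages).}
#'   \item{allsites_vcf}{all-sites VCF for diversity statistics.}
#'   \item{meta}{samples CSV (required with `vcf`): sample, population,
#'     site, lat/lon or x/y.}
#'   \item{densities}{CSV site, count, area_m2, taxon_fraction.}
#'   \item{ne_table}{CSV population, ne, extent.}
#'   \item{dadi_params}{CSV theta, nu1, nu2, M12, M21, T, L.}
#'   \item{filters}{list(mac, depth_min, depth_max, site_miss, sample_miss,
#'     maf, clone_threshold).}
#'   \item{prune}{list(window, step, vif_max) or `FALSE` to skip.}
#'   \item{ibd}{list(model = "2D"/"1D", mode = "haversine"/"planar",
#'     min_distance, max_distance, n_boot, n_perm).}
#'   \item{dispersal}{list(model, strip_width, n_mc).}
#'   \item{diversity}{list(window, g, min_n).}
#'   \item{ne}{list(maf_cutoff).}
#'   \item{demography}{list(mu, g).}
#'   \item{seed}{integer (default 1).}
#' }
#'
#' @param config list or JSON file path.
#' @param out_dir output directory (created).
#' @return Invisibly, a list of stage results; also writes `manifest.json`
#'   and stage outputs under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  notice <- function(...) message("[dispersalkit] ", sprintf(...))
  results <- list()

  inputs <- unlist(config[intersect(names(config),
                                    c("vcf", "allsites_vcf", "meta",
                                      "densities", "ne_table", "dadi_params"))])
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) stop("missing input file(s): ",
                               paste(missing_in, collapse = ", "))

  gm <- NULL
  st <- NULL
  if (!is.null(config$vcf)) {
    if (is.null(config$meta)) stop("'meta' samples CSV is required with 'vcf'")
    fl <- config$filters %||% list()
    gm <- read_genotypes(config$vcf, mode = "variant")
    st <- read_sample_table(config$meta)
    gm <- filter_sites(gm, mac_min = fl$mac %||% 3,
                       depth_min = fl$depth_min %||% 5,
                       depth_max = fl$depth_max %||% 100,
                       max_site_missing = fl$site_miss %||% 0.5,
                       maf_min = fl$maf %||% 0.01)
    gm <- filter_samples(gm, max_sample_missing = fl$sample_miss %||% 0.3)
    sim <- allelic_similarity(gm)
    rep_ <- detect_clones(sim, sample_missingness(gm),
                          threshold = fl$clone_threshold %||% 0.99)
    write_clonal_report(rep_, file.path(out_dir, "clones.json"))
    if (length(rep_$removed)) {
      gm <- gm_subset(gm, samples = setdiff(gm$samples, rep_$removed))
      # clone removal changes allele counts: re-apply site filters and log both
      n_before <- nrow(gm$loci)
      gm <- filter_sites(gm, mac_min = fl$mac %||% 3,
                         depth_min = fl$depth_min %||% 5,
                         depth_max = fl$depth_max %||% 100,
                         max_site_missing = fl$site_miss %||% 0.5,
                         maf_min = fl$maf %||% 0.01)
      notice("re-applied site filters after clone removal: %d -> %d sites",
             n_before, nrow(gm$loci))
    }
    if (!isFALSE(config$prune)) {
      pr <- config$prune %||% list()
      gm <- prune_linked(gm, window = pr$window %||% 50,
                         step = pr$step %||% 5, vif_max = pr$vif_max %||% 2)
    }
    st <- st[st$sample %in% gm$samples, , drop = FALSE]
    write_genotype_tsv(gm, file.path(out_dir, "genotypes_filtered.tsv"))
    results$filter <- list(n_samples = length(gm$samples), n_sites = nrow(gm$loci),
                           clones_removed = rep_$removed)
  } else notice("no 'vcf' input: genotype stages skipped")

  fit <- NULL
  if (!is.null(gm) && !is.null(st) &&
      (all(c("lat", "lon") %in% names(st)) || all(c("x", "y") %in% names(st)))) {
    ib <- config$ibd %||% list()
    mode <- ib$mode %||% (if (all(c("x", "y") %in% names(st))) "planar" else "haversine")
    fit <- ibd_analysis(gm, st, model = ib$model %||% "2D",
                        min_distance = ib$min_distance %||% 1,
                        max_distance = ib$max_distance %||% Inf,
                        mode = mode, n_boot = ib$n_boot %||% 1000,
                        n_perm = ib$n_perm %||% 999, seed = seed)
    jsonlite::write_json(fit[c("model", "b", "intercept", "ci_low", "ci_high",
                               "n_pairs", "p_value")],
                         file.path(out_dir, "ibd.json"),
                         auto_unbox = TRUE, digits = NA)
    results$ibd <- fit
  } else notice("no coordinates: IbD stage skipped")

  if (!is.null(fit) && !is.null(config$densities)) {
    dd <- utils::read.csv(config$densities, stringsAsFactors = FALSE)
    dp <- config$dispersal %||% list()
    model <- dp$model %||% (config$ibd$model %||% "2D")
    dens <- census_density(dd$count, dd$area_m2,
                           taxon_fraction = dd$taxon_fraction %||% 1,
                           model = model, strip_width = dp$strip_width %||% 1,
                           seed = seed)
    disp <- propagate_sigma(fit$boot_draws, dens, model = model,
                            n_mc = dp$n_mc %||% 10000, seed = seed)
    jsonlite::write_json(disp[c("model", "sigma", "ns", "radius",
                                "kernel_mean_distance", "sigma_modes")],
                         file.path(out_dir, "dispersal.json"),
                         auto_unbox = TRUE, digits = NA)
    results$dispersal <- disp
  } else notice("no 'densities' input or no IbD fit: dispersal stage skipped")

  if (!is.null(config$allsites_vcf) && !is.null(config$meta)) {
    dv <- config$diversity %||% list()
    gma <- read_genotypes(config$allsites_vcf, mode = "all-sites")
    st2 <- read_sample_table(config$meta)
    pm <- data.frame(sample = st2$sample, population = st2$population)
    pm <- pm[pm$sample %in% gma$samples, , drop = FALSE]
    div <- diversity_report(gm_subset(gma, samples = pm$sample), pm,
                            window = dv$window %||% 1000,
                            g = dv$g %||% "auto", min_n = dv$min_n %||% 8)
    utils::write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
    results$diversity <- div
  } else notice("no 'allsites_vcf' input: diversity stage skipped")

  if (!is.null(gm) && !is.null(st) && "population" %in% names(st)) {
    pm <- data.frame(sample = st$sample, population = st$population)
    ne_cfg <- config$ne %||% list()
    pops <- unique(pm$population)
    ne_rows <- lapply(pops, function(p) {
      est <- tryCatch(estimate_ne(gm, pop = pm$sample[pm$population == p],
                                  maf_cutoff = ne_cfg$maf_cutoff %||% 0.02),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      data.frame(population = p, ne = est$ne, r2_mean = est$r2_mean,
                 n_pairs = est$n_pairs)
    })
    ne_df <- do.call(rbind, ne_rows)
    if (!is.null(ne_df)) {
      utils::write.csv(ne_df, file.path(out_dir, "ne.csv"), row.names = FALSE)
      results$ne <- ne_df
    }
    if (length(pops) >= 2 && all(table(pm$population) >= 2)) {
      fst <- pairwise_fst(gm, pm)
      utils::write.table(fst, file.path(out_dir, "fst.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      results$fst <- fst
    }
  }

  if (!is.null(config$dadi_params)) {
    dm <- config$demography %||% list()
    demog <- convert_params_table(config$dadi_params,
                                  mu = dm$mu %||% 1.2e-8, g = dm$g %||% 3)
    utils::write.csv(demog, file.path(out_dir, "demography.csv"),
                     row.names = FALSE)
    results$demography <- demog
  } else notice("no 'dadi_params' input: demography stage skipped")

  manifest <- list(
    package = "dispersalkit",
    version = as.character(utils::packageVersion("dispersalkit")),
    r_version = as.character(getRversion()),
    seed = seed,
    config = config[setdiff(names(config), "")],
    input_md5 = as.list(tools::md5sum(inputs)),
    stages_run = names(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
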