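# End-to-end orchestration: simulate/load -> alpha & sectors -> beta ->
# biochemistry & Mantel -> CAGs & over-abundance -> sector networks, with a
# provenance manifest and content-hash stage caching.

#' Pipeline configuration
#'
#' All thresholds and permutation counts of the pipeline in one validated
#' object.  Water and sediment are processed as independent branches of the
#' same flow.
#'
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @param inputs optional named list of file paths (\code{abundance},
#'   \code{metadata}, \code{tree}, \code{biochem}); when absent the
#'   synthetic generator is used.
#' @param design \code{\link{synthetic_design}} used when simulating.
#' @param n_perm_permanova,n_perm_mantel,n_perm_network,n_null_cohesion
#'   permutation/shuffle counts.
#' @param k_cags number of co-abundance groups per realm (default 3).
#' @param edge_q FDR threshold for network edges.
#' @param bold_threshold over-abundance bold display tier.
#' @param r2_threshold biological-relevance threshold for the axis screen.
#' @param hub_quantile centrality quantile for hub calling.
#' @param grid_res TIN grid resolution (nodes per axis).
#' @param exclusivity_ratio mean relative-abundance ratio above which an
#'   order counts as realm-exclusive in the cross-realm report.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, inputs = NULL,
                            design = synthetic_design(),
                            n_perm_permanova = 999, n_perm_mantel = 9999,
                            n_perm_network = 1000, n_null_cohesion = 200,
                            k_cags = 3, edge_q = 0.05, bold_threshold = 1.3,
                            r2_threshold = 0.25, hub_quantile = 0.90,
                            grid_res = 50, exclusivity_ratio = 10) {
  assert_that(is_number(seed), "seed must be a single number")
  assert_that(edge_q > 0 && edge_q <= 1, "edge_q outside (0, 1]")
  assert_that(r2_threshold >= 0 && r2_threshold <= 1,
              "r2_threshold outside [0, 1]")
  assert_that(hub_quantile > 0 && hub_quantile < 1,
              "hub_quantile outside (0, 1)")
  assert_that(bold_threshold >= 1, "bold_threshold below 1")
  assert_that(all(c(n_perm_permanova, n_perm_mantel, n_perm_network,
                    n_null_cohesion) >= 1), "permutation counts must be >= 1")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the \code{\link{pipeline_config}}
#'   arguments (design fields nested under \code{design}).
#' @return pipeline_config.
#' @export
load_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) y$design <- do.call(synthetic_design, y$design)
  do.call(pipeline_config, y)
}

config_fingerprint <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes every stage and writes its outputs plus \code{manifest.json}
#' (parameters, seeds, per-stage input fingerprints and output checksums)
#' under \code{out}.  A stage whose fingerprint matches the previous
#' manifest and whose outputs still exist is skipped, so a rerun with an
#' unchanged configuration is a no-op and a changed seed recomputes only
#' the stochastic stages.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out, quiet = FALSE) {
  assert_that(inherits(config, "pipeline_config"), "not a pipeline_config")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    jsonlite::fromJSON(manifest_path, simplifyVector = FALSE) else list()
  manifest <- list(package_version = as.character(utils::packageVersion("pelnet")),
                   seed = config$seed, stages = list())
  say <- function(...) if (!quiet) message("[pelnet] ", ...)

  run_stage <- function(name, fingerprint, outputs, fun) {
    old <- old_manifest$stages[[name]]
    paths <- file.path(out, outputs)
    if (!is.null(old) && identical(old$fingerprint, fingerprint) &&
        all(file.exists(paths))) {
      say("stage ", name, ": cached, skipping")
      manifest$stages[[name]] <<- old
      return(invisible(NULL))
    }
    say("stage ", name)
    fun(paths)
    manifest$stages[[name]] <<- list(
      fingerprint = fingerprint, outputs = outputs,
      checksums = unname(tools::md5sum(paths)))
    invisible(NULL)
  }

  # ---- stage: data (simulate or load) ---------------------------------
  if (is.null(config$inputs)) {
    fp <- config_fingerprint(stage = "simulate", seed = config$seed,
                             design = unclass(config$design))
    data_files <- c("abundance.tsv", "metadata.tsv", "tree.nwk",
                    "biochem.tsv", "ground_truth.tsv")
    run_stage("data", fp, data_files, function(paths) {
      ds <- generate_dataset(config$design, seed = config$seed)
      write_abundance_table(ds$abundance, paths[1])
      write_tsv(ds$metadata, paths[2])
      write_newick(ds$tree, paths[3])
      write_tsv(ds$biochem, paths[4])
      write_tsv(planted_truth_report(ds$ground_truth), paths[5])
    })
  } else {
    fp <- config_fingerprint(stage = "load",
                             sums = unname(tools::md5sum(unlist(config$inputs))))
    data_files <- c("abundance.tsv", "metadata.tsv", "tree.nwk", "biochem.tsv")
    run_stage("data", fp, data_files, function(paths) {
      file.copy(config$inputs$abundance, paths[1], overwrite = TRUE)
      file.copy(config$inputs$metadata, paths[2], overwrite = TRUE)
      file.copy(config$inputs$tree, paths[3], overwrite = TRUE)
      if (!is.null(config$inputs$biochem))
        file.copy(config$inputs$biochem, paths[4], overwrite = TRUE)
    })
  }
  tab <- read_abundance_table(file.path(out, "abundance.tsv"))
  meta <- read_sample_metadata(file.path(out, "metadata.tsv"))
  tab$realm <- setNames(meta$realm, meta$sample_id)[sample_ids(tab)]
  tree <- read_newick(file.path(out, "tree.nwk"))
  biochem <- if (file.exists(file.path(out, "biochem.tsv")))
    read_biochem_table(file.path(out, "biochem.tsv")) else NULL
  data_sums <- unname(tools::md5sum(file.path(out, data_files)))
  sectors <- setNames(meta$sector, meta$sample_id)

  for (realm in c("water", "sediment")) {
    ids <- meta$sample_id[meta$realm == realm]
    rt <- subset_samples(tab, ids)
    rmeta <- meta[meta$realm == realm, ]
    tag <- function(f) paste0(realm, "_", f)

    # ---- alpha diversity, quartiles, sectors, TIN ---------------------
    fp <- config_fingerprint(stage = "alpha", realm = realm, data = data_sums,
                             grid = config$grid_res)
    run_stage(tag("alpha"), fp,
              c(tag("alpha.tsv"), tag("sector_report.tsv"), tag("tin_grid.tsv")),
              function(paths) {
      alpha <- assign_quartiles(alpha_diversity(rt))
      write_tsv(alpha, paths[1])
      rules <- default_sector_rules(realm)
      rules <- rules[vapply(rules, function(r)
        r$sector %in% rmeta$sector, TRUE)]
      write_tsv(validate_sectors(alpha, sectors, rules), paths[2])
      pts <- data.frame(lon = rmeta$longitude, lat = rmeta$latitude,
                        shannon = alpha$shannon[match(rmeta$sample_id,
                                                      alpha$sample_id)])
      surf <- tin_interpolate(pts, grid_res = config$grid_res)
      write_tsv(surf$grid, paths[3])
    })

    # ---- beta diversity -----------------------------------------------
    fp <- config_fingerprint(stage = "beta", realm = realm, data = data_sums,
                             seed = config$seed,
                             n_perm = config$n_perm_permanova,
                             r2 = config$r2_threshold)
    run_stage(tag("beta"), fp,
              c(tag("unifrac.tsv"), tag("pcoa.tsv"), tag("permanova.tsv"),
                tag("axis_screen.tsv")),
              function(paths) {
      du <- unweighted_unifrac(to_relative(rt), tree)
      write_tsv(cbind(sample_id = rownames(du), as.data.frame(du)), paths[1])
      ord <- pcoa(du)
      write_tsv(cbind(sample_id = rownames(ord$coordinates),
                      as.data.frame(ord$coordinates)), paths[2])
      pm <- permanova(du, sectors[ids], n_perm = config$n_perm_permanova,
                      seed = config$seed)
      write_tsv(as.data.frame(pm), paths[3])
      cov <- data.frame(depth_m = rmeta$depth_m,
                        distance_from_coast_km = rmeta$distance_from_coast_km,
                        row.names = rmeta$sample_id)
      if (realm == "sediment" && !is.null(biochem)) {
        bio <- biochem[match(rmeta$sample_id, biochem$sample_id),
                       c("PRT", "CHO", "LIP", "PIG", "BPC")]
        cov <- cbind(cov, bio)
      }
      write_tsv(axis_environment_screen(ord, cov,
                                        r2_threshold = config$r2_threshold),
                paths[4])
    })

    # ---- CAGs and over-abundance --------------------------------------
    fp <- config_fingerprint(stage = "cags", realm = realm, data = data_sums,
                             k = config$k_cags, edge_q = config$edge_q,
                             bold = config$bold_threshold)
    secs <- sort(unique(rmeta$sector))
    run_stage(tag("cags"), fp,
              c(tag("kendall_tau.tsv"), tag("cag_membership.tsv"),
                tag("over_abundance.tsv"), tag("wiggum_overall.graphml"),
                paste0(tag("wiggum_"), gsub("[ -]", "", secs), ".graphml")),
              function(paths) {
      rel <- to_relative(rt)
      corr <- kendall_matrix(rel)
      write_tsv(cbind(taxon = rownames(corr$tau), as.data.frame(corr$tau)),
                paths[1])
      part <- cluster_cags(rel, k = config$k_cags)
      write_tsv(data.frame(taxon = names(part$membership),
                           cag = unname(part$membership)), paths[2])
      prof <- over_abundance(rel, sectors,
                             bold_threshold = config$bold_threshold)
      oa <- do.call(rbind, lapply(rownames(prof$ratio), function(s)
        data.frame(sector = s, taxon = colnames(prof$ratio),
                   over_abundance = prof$ratio[s, ], tier = prof$tier[s, ],
                   row.names = NULL)))
      write_tsv(oa, paths[3])
      write_network(build_wiggum(rel, part, corr, edge_q = config$edge_q),
                    paths[4], format = "graphml")
      for (si in seq_along(secs))
        write_network(build_wiggum(rel, part, corr, profile = prof,
                                   sector = secs[si],
                                   edge_q = config$edge_q),
                      paths[4 + si], format = "graphml")
    })

    # ---- sector co-occurrence networks --------------------------------
    fp <- config_fingerprint(stage = "networks", realm = realm,
                             data = data_sums, seed = config$seed,
                             n_perm = config$n_perm_network,
                             n_null = config$n_null_cohesion,
                             hub_q = config$hub_quantile,
                             edge_q = config$edge_q)
    run_stage(tag("networks"), fp,
              c(tag("network_summary.tsv"),
                paste0(tag("network_"), gsub("[ -]", "", secs), ".graphml")),
              function(paths) {
      rows <- list()
      for (si in seq_along(secs)) {
        st <- subset_samples(rt, rmeta$sample_id[rmeta$sector == secs[si]])
        net <- infer_network(st, n_perm = config$n_perm_network,
                             edge_q = config$edge_q, seed = config$seed)
        write_network(net, paths[1 + si], format = "graphml")
        rows[[si]] <- network_summary(st, sector = secs[si], net = net,
                                      seed = config$seed,
                                      n_null = config$n_null_cohesion,
                                      hub_quantile = config$hub_quantile)
      }
      write_tsv(do.call(rbind, rows), paths[1])
    })
  }

  # ---- Mantel tests: sediment community vs biochemistry ---------------
  if (!is.null(biochem)) {
    fp <- config_fingerprint(stage = "mantel", data = data_sums,
                             seed = config$seed,
                             n_perm = config$n_perm_mantel)
    run_stage("mantel", fp, "mantel.tsv", function(paths) {
      ids <- meta$sample_id[meta$realm == "sediment"]
      du <- unweighted_unifrac(to_relative(subset_samples(tab, ids)), tree)
      bio <- biochem[match(ids, biochem$sample_id), ]
      rows <- lapply(c("CHO", "PRT", "LIP", "PIG"), function(v) {
        dv <- as.matrix(dist(bio[[v]]))
        dimnames(dv) <- list(ids, ids)
        m <- mantel(du, dv, method = "spearman",
                    n_perm = config$n_perm_mantel, seed = config$seed)
        data.frame(covariate = v, mantel_r = m$statistic,
                   p_value = m$p_value, n_perm = m$n_perm)
      })
      write_tsv(do.call(rbind, rows), paths[1])
    })
  }

  # ---- cross-realm shared vs exclusive orders -------------------------
  fp <- config_fingerprint(stage = "realm_overlap", data = data_sums,
                           ratio = config$exclusivity_ratio)
  run_stage("realm_overlap", fp, "realm_overlap.tsv", function(paths) {
    write_tsv(realm_overlap_report(tab, config$exclusivity_ratio), paths[1])
  })

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), manifest_path)
  invisible(manifest)
}

#' Shared vs realm-exclusive orders
#'
#' Compares each taxon's mean relative abundance between realms; a taxon is
#' exclusive to a realm when its mean there exceeds the other realm's mean
#' by more than \code{ratio} to 1 (taxa absent from one realm count as
#' exclusive to the other).
#'
#' @param t abundance_table with realm annotations.
#' @param ratio exclusivity ratio threshold (default 10).
#' @return data.frame: taxon, mean abundance per realm, status
#'   shared/water-exclusive/sediment-exclusive/absent.
#' @export
realm_overlap_report <- function(t, ratio = 10) {
  assert_that(!is.null(t$realm), "table lacks realm annotations")
  rel <- if (t$is_relative) t else to_relative(t)
  mw <- rowMeans(rel$values[, rel$realm == "water", drop = FALSE])
  ms <- rowMeans(rel$values[, rel$realm == "sediment", drop = FALSE])
  status <- ifelse(mw == 0 & ms == 0, "absent",
            ifelse(ms == 0 | (mw > 0 & mw / pmax(ms, .Machine$double.xmin) > ratio),
                   "water-exclusive",
            ifelse(mw == 0 | ms / pmax(mw, .Machine$double.xmin) > ratio,
                   "sediment-exclusive", "shared")))
  data.frame(taxon = taxa_ids(rel), mean_water = mw, mean_sediment = ms,
             status = status, row.names = NULL, stringsAsFactors = FALSE)
}
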