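# Seeded synthetic datasets with the statistical structure the pipeline
# assumes: co-abundance blocks (latent factor correlation), spatial sectors
# with log-fold abundance shifts, planted hub taxa inside sectors, and
# biochemical gradients coupled to the compositional gradient.
#
# Counts are drawn by a logistic-normal-multinomial: a latent Gaussian
# vector with block covariance is softmax-transformed to proportions and
# sampled at a lognormal sequencing depth.  This (rather than a Dirichlet)
# is used because the co-abundance stage needs an explicitly plantable
# correlation structure.

#' Synthetic study design
#'
#' Defaults emulate the field campaign the pipeline is built around:
#' 19 water-column and 25 sediment samples over a ~130 km^2 coastal area,
#' order-level composition with 3 co-abundance blocks, 3 sectors per realm
#' (water: North/Central/South latitude bands; sediment: South band plus a
#' North-West/North-East split) with planted over-abundance shifts, one
#' planted hub taxon per sector, and north-increasing biochemical gradients.
#'
#' @param n_water,n_sediment sample counts per realm.
#' @param n_taxa number of order-level taxa (split into \code{n_blocks}
#'   equal co-abundance blocks).
#' @param n_blocks number of planted co-abundance blocks.
#' @param rho_within,rho_between latent correlations inside/between blocks
#'   (\code{rho_within > rho_between >= 0}).
#' @param sector_effect log-fold shift applied to one block per sector.
#' @param gradient_effect scale of the continuous north-south compositional
#'   gradient: per-taxon loadings (standard normal, fixed by the seed) are
#'   multiplied by this and by the sample's centred northness and added to
#'   the latent log abundances, tying composition to latitude, water depth,
#'   distance from coast and the biochemical gradients.
#' @param n_hub_satellites satellites coupled to each planted hub.
#' @param hub_coupling latent correlation between hub and satellites inside
#'   the hub's sector.
#' @param sigma_latent standard deviation of the latent log-abundance noise.
#' @param depth_meanlog,depth_sdlog lognormal sequencing-depth parameters.
#' @param bbox study bounding box (lon_min, lon_max, lat_min, lat_max).
#' @return a \code{synthetic_design} list.
#' @export
synthetic_design <- function(n_water = 19, n_sediment = 25, n_taxa = 60,
                             n_blocks = 3, rho_within = 0.8,
                             rho_between = 0, sector_effect = 1.0,
                             gradient_effect = 1.0,
                             n_hub_satellites = 4, hub_coupling = 0.9,
                             sigma_latent = 1.0,
                             depth_meanlog = log(2e4), depth_sdlog = 0.3,
                             bbox = c(lon_min = 12.72288889,
                                      lon_max = 12.90647222,
                                      lat_min = 44.0686667,
                                      lat_max = 44.2524444)) {
  assert_that(rho_within > rho_between && rho_between >= 0,
              "need rho_within > rho_between >= 0")
  assert_that(rho_within < 1, "rho_within must be < 1")
  assert_that(n_taxa >= 2 * n_blocks, "too few taxa for the block design")
  assert_that(n_blocks * (1 + n_hub_satellites) * 2 <= n_taxa,
              "more hubs/satellites than taxa can accommodate")
  structure(as.list(environment()), class = "synthetic_design")
}

sector_bands <- function(realm, bbox) {
  lat_cuts <- seq(bbox[["lat_min"]], bbox[["lat_max"]], length.out = 4)
  lon_mid <- mean(bbox[c("lon_min", "lon_max")])
  if (realm == "water")
    list(South   = c(bbox[["lon_min"]], bbox[["lon_max"]], lat_cuts[1], lat_cuts[2]),
         Central = c(bbox[["lon_min"]], bbox[["lon_max"]], lat_cuts[2], lat_cuts[3]),
         North   = c(bbox[["lon_min"]], bbox[["lon_max"]], lat_cuts[3], lat_cuts[4]))
  else
    list(South        = c(bbox[["lon_min"]], bbox[["lon_max"]], lat_cuts[1], lat_cuts[2]),
         `North-West` = c(bbox[["lon_min"]], lon_mid, lat_cuts[2], lat_cuts[4]),
         `North-East` = c(lon_mid, bbox[["lon_max"]], lat_cuts[2], lat_cuts[4]))
}

split_sizes <- function(n, k) {
  s <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) s[seq_len(extra)] <- s[seq_len(extra)] + 1L
  s
}

# latent factor draw with block structure: corr rho_within inside a block,
# rho_between across blocks
draw_latent <- function(n, blocks, rho_w, rho_b, sigma) {
  p <- length(blocks)
  a <- sqrt(rho_w - rho_b); cshared <- sqrt(rho_b)
  resid <- sqrt(1 - rho_w)
  f <- matrix(rnorm(n * max(blocks)), n, max(blocks))
  g <- rnorm(n)
  e <- matrix(rnorm(n * p), n, p)
  z <- a * f[, blocks, drop = FALSE] + cshared * g + resid * e
  z * sigma
}

#' Generate a full synthetic dataset
#'
#' @param design a \code{\link{synthetic_design}}.
#' @param seed integer seed; the same seed reproduces the dataset bitwise.
#' @return list with \code{abundance} (counts abundance_table over both
#'   realms), \code{metadata} (sample data.frame incl. sector), \code{tree}
#'   (random coalescent over the taxa), \code{biochem} (sediment samples),
#'   and \code{ground_truth} (planted blocks, shifts, hubs, gradients).
#' @export
generate_dataset <- function(design, seed = 1L) {
  assert_that(inherits(design, "synthetic_design"), "not a synthetic_design")
  d <- design
  taxa <- sprintf("Order%03d", seq_len(d$n_taxa))
  blocks <- rep(seq_len(d$n_blocks), length.out = d$n_taxa)
  blocks <- sort(blocks)
  names(blocks) <- taxa

  # -- coordinates and sectors ------------------------------------------
  set.seed(derive_seed(seed, 1L))
  meta <- list(); counts <- list()
  truth_hubs <- list()
  sector_shift <- list()
  gradient_load <- list()
  for (realm in c("water", "sediment")) {
    n <- if (realm == "water") d$n_water else d$n_sediment
    bands <- sector_bands(realm, d$bbox)
    sizes <- split_sizes(n, length(bands))
    rows <- list()
    for (si in seq_along(bands)) {
      b <- bands[[si]]
      ns <- sizes[si]
      rows[[si]] <- data.frame(
        sector = names(bands)[si],
        longitude = runif(ns, b[1], b[2]),
        latitude = runif(ns, b[3], b[4]), stringsAsFactors = FALSE)
    }
    rows <- do.call(rbind, rows)
    northness <- (rows$latitude - d$bbox[["lat_min"]]) /
      (d$bbox[["lat_max"]] - d$bbox[["lat_min"]])
    rows$sample_id <- sprintf("%s%02d", if (realm == "water") "W" else "S",
                              seq_len(n))
    rows$realm <- realm
    rows$depth_m <- pmax(5, 10 + 28 * northness + rnorm(n, 0, 1.5))
    rows$distance_from_coast_km <- pmax(5, 13.5 + 10 * northness +
                                          rnorm(n, 0, 0.8))
    meta[[realm]] <- rows

    # -- latent composition ---------------------------------------------
    set.seed(derive_seed(seed, 2L + match(realm, c("water", "sediment"))))
    # realm-specific baseline; the wide spread makes rare orders drop in and
    # out of detection, as in real order-level tables
    mu <- rnorm(d$n_taxa, 0, 2.5)
    # zero-mean latent fluctuations with block covariance; hub coupling is
    # applied to these residuals (not to the means) so planting a hub never
    # shifts a satellite's marginal abundance
    eps <- draw_latent(n, blocks, d$rho_within, d$rho_between, d$sigma_latent)
    # planted hubs: hub + satellites inside the hub's sector
    # hubs sit on each block's dominant members (hub orders are abundant
    # taxa in practice); water takes the odd abundance ranks and sediment
    # the even ones, so the realms use disjoint but comparably abundant taxa
    rank_seq <- seq(if (realm == "water") 1L else 2L,
                    by = 2L, length.out = 1L + d$n_hub_satellites)
    for (si in seq_along(bands)) {
      blk <- (si - 1L) %% d$n_blocks + 1L
      members <- which(blocks == blk)
      members <- members[order(mu[members], decreasing = TRUE)]
      slots <- members[rank_seq]
      hub <- slots[1L]; sats <- slots[-1L]
      in_sec <- rows$sector == names(bands)[si]
      for (s_ in sats) {
        eps[in_sec, s_] <- d$hub_coupling * eps[in_sec, hub] +
          sqrt(1 - d$hub_coupling^2) * eps[in_sec, s_]
      }
      truth_hubs[[paste(realm, names(bands)[si])]] <- data.frame(
        realm = realm, sector = names(bands)[si], hub = taxa[hub],
        satellites = paste(taxa[sats], collapse = ";"),
        stringsAsFactors = FALSE)
    }
    # assemble latent log abundances: baseline + sector shift + gradient +
    # (hub-coupled) fluctuations, then softmax -> multinomial counts
    shift <- matrix(0, length(bands), d$n_taxa,
                    dimnames = list(names(bands), taxa))
    for (si in seq_along(bands)) {
      tgt <- blocks == ((si - 1L) %% d$n_blocks + 1L)
      shift[si, tgt] <- d$sector_effect
    }
    sector_shift[[realm]] <- shift
    grad_load <- rnorm(d$n_taxa) * d$gradient_effect
    gradient_load[[realm]] <- setNames(grad_load, taxa)
    z <- sweep(eps, 2L, mu, "+") + shift[rows$sector, , drop = FALSE] +
      (northness - 0.5) %o% grad_load
    props <- exp(z)
    props <- props / rowSums(props)
    depth <- pmax(2000, round(rlnorm(n, d$depth_meanlog, d$depth_sdlog)))
    cts <- vapply(seq_len(n), function(i)
      rmultinom(1, depth[i], props[i, ])[, 1L], integer(d$n_taxa))
    dimnames(cts) <- list(taxa, rows$sample_id)
    counts[[realm]] <- cts
  }

  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  values <- cbind(counts$water, counts$sediment)
  tab <- abundance_table(values, is_relative = FALSE,
                         realm = setNames(meta$realm, meta$sample_id))

  # -- phylogeny: random coalescent over the taxa ------------------------
  set.seed(derive_seed(seed, 7L))
  tree <- ape::rcoal(d$n_taxa, tip.label = taxa)

  # -- sediment biochemistry coupled to the northness gradient ----------
  set.seed(derive_seed(seed, 8L))
  sed <- meta[meta$realm == "sediment", ]
  u <- (sed$latitude - d$bbox[["lat_min"]]) /
    (d$bbox[["lat_max"]] - d$bbox[["lat_min"]])
  ns <- nrow(sed)
  biochem <- data.frame(
    sample_id = sed$sample_id,
    PRT = pmax(0.2, 2.8 + 2.8 * u + rnorm(ns, 0, 0.8)),
    CHO = pmax(0.05, 0.40 + 0.50 * u + rnorm(ns, 0, 0.12)),
    LIP = pmax(0.05, 0.45 + 0.60 * u + rnorm(ns, 0, 0.15)),
    CHLA = pmax(0.02, 0.60 + 1.20 * u + rnorm(ns, 0, 0.25)),
    PHEO = pmax(0.50, 10.0 + 9.0 * u + rnorm(ns, 0, 2.5)),
    stringsAsFactors = FALSE)
  biochem <- augment_biochem(biochem)

  ground_truth <- list(
    blocks = data.frame(taxon = taxa, block = unname(blocks),
                        stringsAsFactors = FALSE),
    sector_shift = sector_shift,
    gradient_load = gradient_load,
    hubs = do.call(rbind, c(truth_hubs, list(make.row.names = FALSE))),
    gradient = "latitude (northness) drives sector shifts, water depth, distance from coast and all biochemical concentrations",
    design = d, seed = seed)

  list(abundance = tab, metadata = meta, tree = tree, biochem = biochem,
       ground_truth = ground_truth)
}

#' Machine-readable planted-truth table
#'
#' One row per taxon: its co-abundance block, whether it is a planted hub
#' (and in which realm/sector), and its planted log-fold shift in every
#' sector of each realm.  Consumed by the recovery tests (ARI for CAGs, hub
#' hit rate, sign of over-abundance shifts).
#'
#' @param ground_truth the \code{ground_truth} element of
#'   \code{\link{generate_dataset}}.
#' @return data.frame, one row per taxon.
#' @export
planted_truth_report <- function(ground_truth) {
  gt <- ground_truth
  out <- gt$blocks
  hub_of <- setNames(paste(gt$hubs$realm, gt$hubs$sector, sep = ":"),
                     gt$hubs$hub)
  out$hub_sector <- unname(hub_of[out$taxon])
  for (realm in names(gt$sector_shift)) {
    sh <- gt$sector_shift[[realm]]
    for (s in rownames(sh))
      out[[paste0("shift_", substr(realm, 1, 3), "_", gsub("[ -]", "", s))]] <-
        sh[s, out$taxon]
  }
  out
}
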