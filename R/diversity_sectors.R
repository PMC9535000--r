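# Shannon alpha diversity, quartile ranks and sector validation.
#
# Sectors are contiguous sub-areas of the sampling grid defined a priori
# (from the interpolated diversity map); their coherence is checked against
# quartile-composition rules such as "at least 70% of the sector's samples
# fall in the 3rd and 4th diversity quartiles".

#' Shannon diversity of one relative-abundance vector
#'
#' Natural-log Shannon entropy \eqn{H = -\sum_{p_i>0} p_i \log p_i} (nats).
#'
#' @param p non-negative vector summing to 1 within 1e-9.
#' @return H in nats.
#' @export
shannon <- function(p) {
  assert_that(all(p >= 0), "relative abundances must be non-negative")
  assert_that(abs(sum(p) - 1) < 1e-9,
              "input is not normalized (sums to ", format(sum(p)), ")")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon diversity for every sample of a table
#'
#' @param t abundance_table (converted to relative abundances internally).
#' @param rarefy_depth optional sequencing depth; when given and the table
#'   holds counts, each sample is rarefied once to this depth with the
#'   seeded subsample before computing H.
#' @param seed RNG seed used only when rarefying.
#' @return data.frame with sample_id and shannon columns.
#' @export
alpha_diversity <- function(t, rarefy_depth = NULL, seed = 1L) {
  vals <- t$values
  if (!is.null(rarefy_depth)) {
    assert_that(!t$is_relative, "cannot rarefy a relative-abundance table")
    assert_that(all(colSums(vals) >= rarefy_depth),
                "rarefy depth exceeds the depth of some sample")
    set.seed(derive_seed(seed, 101L))
    vals <- apply(vals, 2L, function(cnt) {
      pool <- rep(seq_along(cnt), cnt)
      tabulate(sample(pool, rarefy_depth), nbins = length(cnt))
    })
    rownames(vals) <- taxa_ids(t)
  }
  rel <- sweep(vals, 2L, colSums(vals), "/")
  data.frame(sample_id = colnames(rel),
             shannon = apply(rel, 2L, shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign diversity quartile ranks within a realm
#'
#' Samples are ranked by Shannon H (ties broken by sample id, so the
#' assignment is deterministic) and split into four consecutive rank groups
#' whose sizes differ by at most one, the 1st quartile holding the lowest
#' diversities.
#'
#' @param alpha data.frame with sample_id and shannon columns (>= 4 rows).
#' @return the same data.frame with an integer \code{quartile} column.
#' @export
assign_quartiles <- function(alpha) {
  n <- nrow(alpha)
  assert_that(n >= 4, "need at least 4 samples to form quartiles")
  ord <- order(alpha$shannon, alpha$sample_id)
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- integer(n)
  q[ord] <- rep(1:4, times = sizes)
  alpha$quartile <- q
  alpha
}

#' A sector composition rule
#'
#' @param sector sector name.
#' @param quartiles integer set of admissible quartiles, e.g. \code{c(3, 4)}.
#' @param min_fraction minimum fraction of the sector's samples that must
#'   fall in those quartiles, in (0, 1].
#' @return a \code{sector_rule} list.
#' @export
sector_rule <- function(sector, quartiles, min_fraction) {
  assert_that(length(quartiles) >= 1 && all(quartiles %in% 1:4),
              "quartile set must be a non-empty subset of 1..4")
  assert_that(min_fraction > 0 && min_fraction <= 1,
              "min_fraction must lie in (0, 1]")
  structure(list(sector = sector, quartiles = as.integer(quartiles),
                 min_fraction = min_fraction), class = "sector_rule")
}

#' Validate sector assignments against quartile-composition rules
#'
#' @param alpha data.frame with sample_id and quartile columns (from
#'   \code{\link{assign_quartiles}}).
#' @param sectors named character vector or data.frame mapping sample_id to
#'   sector.
#' @param rules list of \code{\link{sector_rule}} objects, one per sector.
#' @return data.frame with one row per rule: sector, n, fraction in the
#'   admissible quartiles, threshold, pass flag.
#' @export
validate_sectors <- function(alpha, sectors, rules) {
  if (is.data.frame(sectors))
    sectors <- setNames(sectors$sector, sectors$sample_id)
  assert_that(all(alpha$sample_id %in% names(sectors)),
              "every sample needs a sector")
  secs <- sectors[alpha$sample_id]
  out <- lapply(rules, function(r) {
    in_sec <- secs == r$sector
    if (!any(in_sec))
      stop_pelnet("sector '", r$sector, "' has no samples")
    frac <- mean(alpha$quartile[in_sec] %in% r$quartiles)
    data.frame(sector = r$sector, n = sum(in_sec), fraction = frac,
               quartiles = paste(r$quartiles, collapse = ","),
               threshold = r$min_fraction,
               pass = frac >= r$min_fraction, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default sector rules for the study area
#'
#' Quartile-composition rules for the three pelagic and three benthic
#' alpha-diversity sectors.  The North-West sediment rule's quartile span
#' ("between the 2nd and 4th quartiles") is read as the inclusive set
#' {2, 3, 4}; build your own rules for the strict {2, 4} reading.
#'
#' @param realm \code{"water"} or \code{"sediment"}.
#' @return list of \code{\link{sector_rule}}.
#' @export
default_sector_rules <- function(realm = c("water", "sediment")) {
  realm <- match.arg(realm)
  if (realm == "water")
    list(sector_rule("South",   c(3, 4), 0.70),
         sector_rule("Central", c(1, 2), 1.00),
         sector_rule("North",   c(3, 4), 0.65))
  else
    list(sector_rule("South",      c(1, 2),    0.80),
         sector_rule("North-East", c(3, 4),    0.90),
         sector_rule("North-West", c(2, 3, 4), 0.80))
}
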