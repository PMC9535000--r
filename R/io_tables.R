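#' Construct and validate an abundance table
#'
#' The central container of the pipeline: a taxa-by-samples matrix of counts
#' or relative abundances, with an optional realm (\code{"water"} or
#' \code{"sediment"}) annotation per sample.
#'
#' @param values numeric matrix, taxa in rows, samples in columns, with
#'   unique dimnames.
#' @param is_relative logical; if \code{TRUE} every sample column must sum
#'   to 1 within \code{1e-9}.
#' @param realm optional character vector (one of \code{"water"},
#'   \code{"sediment"} per sample), recycled or named by sample id.
#' @return an object of class \code{abundance_table}.
#' @export
abundance_table <- function(values, is_relative = FALSE, realm = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(nrow(values) >= 2L && ncol(values) >= 2L,
              "need at least 2 taxa and 2 samples")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry taxon and sample names")
  assert_that(!anyDuplicated(rownames(values)), "duplicate taxon ids")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids")
  if (anyNA(values) || any(values < 0)) {
    bad <- which(is.na(values) | values < 0, arr.ind = TRUE)[1L, ]
    stop_pelnet("negative or missing abundance at taxon '",
                rownames(values)[bad[1L]], "', sample '",
                colnames(values)[bad[2L]], "'",
                class = "pelnet_validation_error")
  }
  if (is_relative) {
    cs <- colSums(values)
    assert_that(all(abs(cs - 1) < 1e-9),
                "relative-abundance columns must sum to 1 (worst deviation ",
                format(max(abs(cs - 1))), ")")
  }
  if (!is.null(realm)) {
    if (!is.null(names(realm))) realm <- realm[colnames(values)]
    if (length(realm) == 1L) realm <- rep(realm, ncol(values))
    assert_that(length(realm) == ncol(values),
                "realm must have one entry per sample")
    assert_that(all(realm %in% c("water", "sediment")),
                "realm entries must be 'water' or 'sediment'")
    realm <- setNames(as.character(realm), colnames(values))
  }
  structure(list(values = values, is_relative = isTRUE(is_relative),
                 realm = realm),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_relative) "relative" else "counts"))
  if (!is.null(x$realm))
    cat("realms:", paste(sprintf("%s=%d", names(table(x$realm)),
                                 table(x$realm)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

taxa_ids <- function(t) rownames(t$values)
sample_ids <- function(t) colnames(t$values)

#' Subset an abundance table by samples
#'
#' @param t abundance_table.
#' @param samples character vector of sample ids to keep.
#' @return abundance_table restricted to those samples.
#' @export
subset_samples <- function(t, samples) {
  assert_that(all(samples %in% sample_ids(t)),
              "unknown sample id(s): ",
              paste(setdiff(samples, sample_ids(t)), collapse = ", "))
  abundance_table(t$values[, samples, drop = FALSE],
                  is_relative = t$is_relative,
                  realm = if (!is.null(t$realm)) t$realm[samples])
}

#' Read an abundance table from TSV or BIOM-style JSON
#'
#' The TSV dialect is QIIME-like: tab-separated, lines starting with
#' \code{#} ignored except that the last comment line before the body may
#' carry the header; first column holds taxon ids, remaining columns one
#' sample each.  The JSON variant is the minimal dense BIOM layout with
#' \code{rows}, \code{columns} and a dense \code{data} matrix.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"biom-json"}.
#' @param is_relative whether the stored values are relative abundances.
#' @return an \code{\link{abundance_table}}.
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom-json"),
                                 is_relative = FALSE) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: ", path)
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    is_comment <- startsWith(lines, "#")
    body <- lines[!is_comment]
    # QIIME-style headers start with '#'; reuse the last comment line as the
    # header when it is tab-shaped like the body rows.
    if (any(is_comment) && length(body) >= 1L) {
      cand <- sub("^#", "", lines[max(which(is_comment))])
      if (length(strsplit(cand, "\t", fixed = TRUE)[[1L]]) ==
          length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]]))
        body <- c(cand, body)
    }
    assert_that(length(body) >= 2L, "table body too short in ", path)
    cells <- strsplit(body, "\t", fixed = TRUE)
    ncols <- lengths(cells)
    if (length(unique(ncols)) != 1L)
      stop_pelnet("ragged rows in ", path, " (row ",
                  which(ncols != ncols[1L])[1L], ")",
                  class = "pelnet_format_error")
    header <- cells[[1L]]
    samples <- header[-1L]
    if (anyDuplicated(samples))
      stop_pelnet("duplicate sample ids in header of ", path,
                  class = "pelnet_format_error")
    rows <- cells[-1L]
    taxa <- vapply(rows, `[[`, "", 1L)
    if (anyDuplicated(taxa))
      stop_pelnet("duplicate taxon ids in ", path,
                  class = "pelnet_format_error")
    vals <- t(vapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r[-1L]))
      if (anyNA(v))
        stop_pelnet("non-numeric abundance in row '", r[[1L]], "' of ", path,
                    class = "pelnet_format_error")
      v
    }, numeric(length(samples))))
    dimnames(vals) <- list(taxa, samples)
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    assert_that(!is.null(b$rows) && !is.null(b$columns) && !is.null(b$data),
                "not a minimal dense BIOM JSON: ", path)
    vals <- as.matrix(b$data)
    dimnames(vals) <- list(b$rows$id, b$columns$id)
  }
  abundance_table(vals, is_relative = is_relative)
}

#' Write an abundance table as TSV
#'
#' Values are serialised with 17 significant digits, enough for a
#' write/read round-trip to reproduce every double bitwise.
#'
#' @param t abundance_table.
#' @param path output path.
#' @export
write_abundance_table <- function(t, path) {
  vals <- matrix(sprintf("%.17g", t$values), nrow(t$values))
  lines <- c(paste(c("#taxon_id", sample_ids(t)), collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i) {
               paste(taxa_ids(t)[i],
                     paste(vals[i, ], collapse = "\t"), sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Each sample column is divided by its total.  Idempotent on tables that
#' are already relative; zero taxa remain exactly zero.
#'
#' @param t abundance_table.
#' @return abundance_table with \code{is_relative = TRUE}.
#' @export
to_relative <- function(t) {
  cs <- colSums(t$values)
  if (any(cs == 0))
    stop_pelnet("all-zero sample(s): ",
                paste(sample_ids(t)[cs == 0], collapse = ", "))
  abundance_table(sweep(t$values, 2L, cs, "/"), is_relative = TRUE,
                  realm = t$realm)
}

#' Read sample metadata
#'
#' Expects a TSV with columns \code{sample_id}, \code{realm},
#' \code{longitude}, \code{latitude} and optionally \code{depth_m},
#' \code{distance_from_coast_km} and \code{sector}.
#'
#' @param path TSV path.
#' @return a validated data.frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  m <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_metadata(m)
}

validate_sample_metadata <- function(m) {
  need <- c("sample_id", "realm", "longitude", "latitude")
  assert_that(all(need %in% names(m)),
              "metadata missing column(s): ",
              paste(setdiff(need, names(m)), collapse = ", "))
  assert_that(!anyDuplicated(m$sample_id), "duplicate sample ids in metadata")
  assert_that(all(m$realm %in% c("water", "sediment")),
              "realm must be 'water' or 'sediment'")
  assert_that(all(is.finite(m$longitude)) && all(is.finite(m$latitude)),
              "longitude/latitude must be finite")
  if ("depth_m" %in% names(m))
    assert_that(all(is.na(m$depth_m) | m$depth_m > 0),
                "depth_m must be positive where present")
  m
}

#' Read a biochemistry table and recompute derived columns
#'
#' Reads per-sample concentrations of proteins (PRT), carbohydrates (CHO)
#' and lipids (LIP) in mg/g plus chlorophyll-a (CHLA) and phaeopigments
#' (PHEO) in ug/g, and (re)derives total phytopigments
#' \code{PIG = CHLA + PHEO} and biopolymeric carbon
#' \code{BPC = 0.49 PRT + 0.40 CHO + 0.75 LIP} so the stored file can never
#' disagree with the defining identities.
#'
#' @param path TSV path with columns sample_id, PRT, CHO, LIP, CHLA, PHEO.
#' @return data.frame with PIG and BPC columns recomputed.
#' @export
read_biochem_table <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  b <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "PRT", "CHO", "LIP", "CHLA", "PHEO")
  assert_that(all(need %in% names(b)),
              "biochem table missing column(s): ",
              paste(setdiff(need, names(b)), collapse = ", "))
  augment_biochem(b)
}
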