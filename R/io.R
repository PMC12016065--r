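#' Read a beta-value methylation matrix
#'
#' Reads a delimited text file (comma or tab separated, LF or CRLF line
#' endings) with CpG identifiers in the first column and one column per
#' sample, and returns a numeric matrix of DNAm percentages. Values supplied
#' as beta fractions in \[0,1\] are rescaled to percent; `scale = "auto"`
#' multiplies by 100 when the observed maximum is at most 1.5. Missing cells
#' stay `NA` -- nothing is imputed here.
#'
#' @param path Path to the delimited file.
#' @param scale One of `"auto"`, `"fraction"` (values multiplied by 100) or
#'   `"percent"` (values used as-is).
#' @return Numeric matrix (CpG x sample) on the percent scale, with CpG ids
#'   as row names and sample ids as column names.
#' @seealso [write_beta_matrix()], [read_sample_table()]
#' @export
read_beta_matrix <- function(path, scale = c("auto", "fraction", "percent")) {
  scale <- match.arg(scale)
  sep <- detect_separator(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", na.strings = c("NA", ""))
  if (ncol(df) < 2) stop_wkde("beta matrix needs an id column plus >= 1 sample column")
  cpg_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(cpg_ids))
    stop_wkde("duplicate CpG ids in ", path, ": ",
              paste(unique(cpg_ids[duplicated(cpg_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_wkde("duplicate sample ids in ", path, ": ",
              paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop_wkde("non-numeric values in beta matrix ", path)
  dimnames(values) <- list(cpg_ids, sample_ids)

  mx <- suppressWarnings(max(values, na.rm = TRUE))
  if (scale == "fraction" || (scale == "auto" && is.finite(mx) && mx <= 1.5))
    values <- values * 100
  validate_beta_matrix(values)
  values
}

# sniff the delimiter from the header line
detect_separator <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop_wkde("empty file: ", path)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Validate a methylation matrix
#'
#' Checks the percent-scale invariants: unique row/column ids and all
#' non-missing values inside \[0, 100\]. Errors name the first offending cell.
#'
#' @param values Numeric matrix, CpGs as rows.
#' @return The matrix, invisibly.
#' @export
validate_beta_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_wkde("beta matrix must carry CpG row names and sample column names")
  if (anyDuplicated(rownames(values))) stop_wkde("duplicate CpG ids")
  if (anyDuplicated(colnames(values))) stop_wkde("duplicate sample ids")
  bad <- which(!is.na(values) & (values < 0 | values > 100), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_wkde(sprintf("DNAm value %g out of [0, 100] at CpG '%s', sample '%s'",
                      values[i, j], rownames(values)[i], colnames(values)[j]))
  }
  invisible(values)
}

#' Write a beta matrix as tab-separated text
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-exactly.
#'
#' @param values Percent-scale matrix as from [read_beta_matrix()].
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(values, path, sep = "\t") {
  validate_beta_matrix(values)
  chr <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  chr[is.na(values)] <- "NA"
  header <- paste(c("cpg_id", colnames(values)), collapse = sep)
  body <- paste(rownames(values), apply(chr, 1, paste, collapse = sep), sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects columns `sample_id` and `age` (years); optional `sex`
#' (female/male/unknown), `study` and `group` (healthy/diseased/unknown)
#' columns are filled with `"unknown"` when absent.
#'
#' @param path Delimited text file (comma or tab).
#' @return A data.frame with columns sample_id, age, sex, study, group.
#' @export
read_sample_table <- function(path) {
  sep <- detect_separator(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", na.strings = c("NA", ""))
  if (!all(c("sample_id", "age") %in% colnames(df)))
    stop_wkde("sample table must contain columns 'sample_id' and 'age'")
  df$sample_id <- as.character(df$sample_id)
  df$age <- as.numeric(df$age)
  for (col in c("sex", "study", "group"))
    if (is.null(df[[col]])) df[[col]] <- "unknown"
  validate_sample_table(df[, c("sample_id", "age", "sex", "study", "group")])
}

validate_sample_table <- function(samples) {
  if (anyDuplicated(samples$sample_id)) stop_wkde("duplicate sample ids in sample table")
  if (any(!is.finite(samples$age)) || any(samples$age < 0))
    stop_wkde("ages must be finite and >= 0")
  samples
}

#' @rdname read_sample_table
#' @param samples Sample data.frame.
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- model bundle serialization ----------------------------------------

BUNDLE_FORMAT <- "wkdeclock-bundle-1"

#' Save / load a fitted clock model
#'
#' A fitted [wkde] model is stored as a two-file bundle designed to be
#' readable from other languages: `<path>.json` holds all metadata (grid,
#' CpG ids, weights, bandwidths, provenance, payload layout) and
#' `<path>.bin` holds every kernel density matrix as raw little-endian
#' float64, kernel-major, each kernel row-major (DNAm rows x age columns).
#'
#' @param model A `"wkde"` model.
#' @param path Bundle path prefix (extensions are appended).
#' @return `save_wkde` returns `path` invisibly; `load_wkde` returns the
#'   reconstructed model, validated against the model invariants.
#' @export
save_wkde <- function(model, path) {
  validate_wkde(model)
  path <- sub("\\.json$", "", path)
  n <- model$grid$n_points
  meta <- list(
    format = BUNDLE_FORMAT,
    grid = unclass(model$grid),
    cpg_ids = names(model$kernels),
    weights = unname(model$weights),
    bandwidths = lapply(model$kernels, function(k) unname(k$bandwidths)),
    kernel_n = lapply(model$kernels, function(k) k$n),
    provenance = model$provenance,
    payload = list(file = basename(paste0(path, ".bin")), dtype = "float64",
                   endian = "little", order = "kernel-major, row-major (dnam x age)",
                   n_doubles = length(model$kernels) * n * n)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  for (k in model$kernels)
    writeBin(as.vector(t(k$density)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_wkde
#' @export
load_wkde <- function(path) {
  path <- sub("\\.json$", "", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, BUNDLE_FORMAT))
    stop_wkde("unsupported bundle format: ", meta$format %||% "<missing>")
  grid <- do.call(grid_spec, as.list(meta$grid))
  n <- grid$n_points
  cpg_ids <- as.character(meta$cpg_ids)
  n_doubles <- length(cpg_ids) * n * n
  bin_path <- file.path(dirname(paste0(path, ".json")), meta$payload$file)
  raw <- readBin(bin_path, what = "double", n = n_doubles + 1L, size = 8,
                 endian = "little")
  if (length(raw) != n_doubles)
    stop_wkde("kernel payload truncated or inconsistent: expected ",
              n_doubles, " doubles, found ", length(raw))
  kernels <- vector("list", length(cpg_ids))
  for (i in seq_along(cpg_ids)) {
    block <- raw[((i - 1L) * n * n + 1L):(i * n * n)]
    density <- matrix(block, nrow = n, byrow = TRUE,
                      dimnames = list(grid_dnam(grid), grid_ages(grid)))
    bw <- if (is.matrix(meta$bandwidths)) meta$bandwidths[i, ]
          else meta$bandwidths[[i]]
    kernels[[i]] <- new_density_kernel(
      cpg_id = cpg_ids[i], density = density,
      bandwidths = as.numeric(bw),
      n = as.integer(meta$kernel_n[[i]] %||% NA_integer_))
  }
  names(kernels) <- cpg_ids
  weights <- as.numeric(meta$weights)
  names(weights) <- cpg_ids
  model <- new_wkde(grid = grid, kernels = kernels, weights = weights,
                    provenance = meta$provenance)
  validate_wkde(model)
  model
}
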