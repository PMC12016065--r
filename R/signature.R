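#' Remove sex-chromosome and SNP probes
#'
#' Drops CpGs located on chromosomes X or Y and CpGs flagged as
#' single-nucleotide-polymorphism probes, per the supplied annotation.
#' CpGs absent from the annotation are kept with a warning. Row order of
#' the survivors is preserved.
#'
#' @param betas Percent-scale methylation matrix (CpG x sample).
#' @param annotation data.frame with columns `cpg_id`, `chr` and logical
#'   `is_snp`.
#' @return The filtered matrix.
#' @export
filter_probes <- function(betas, annotation) {
  stopifnot(all(c("cpg_id", "chr", "is_snp") %in% colnames(annotation)))
  if (anyDuplicated(annotation$cpg_id)) stop_wkde("duplicate cpg_id in annotation")
  idx <- match(rownames(betas), annotation$cpg_id)
  uncovered <- is.na(idx)
  if (any(uncovered))
    warning(sum(uncovered), " CpG(s) missing from the annotation were kept",
            call. = FALSE)
  chr <- sub("^chr", "", as.character(annotation$chr[idx]))
  drop <- !uncovered & (chr %in% c("X", "Y") |
                          annotation$is_snp[idx] %in% TRUE)
  out <- betas[!drop, , drop = FALSE]
  if (nrow(out) == 0) stop_wkde("probe filtering removed every CpG")
  out
}

#' Squared age correlation per CpG
#'
#' Squared Pearson correlation between DNAm and chronological age, computed
#' per CpG over pairwise-complete observations. CpGs with fewer than
#' `min_n` complete pairs, with zero DNAm variance, or with more than
#' `max_missing_frac` missing values are flagged `NA` (undefined) rather
#' than erroring, so they simply drop out of signature selection.
#'
#' @param betas Percent-scale methylation matrix (CpG x sample).
#' @param samples Sample table; ages matched to matrix columns by
#'   `sample_id`.
#' @param min_n Minimum complete pairs per CpG.
#' @param max_missing_frac CpGs missing a larger fraction are flagged.
#' @return Named numeric vector of r-squared values in \[0,1\], `NA` where
#'   undefined.
#' @export
age_correlation <- function(betas, samples, min_n = 3, max_missing_frac = 0.2) {
  idx <- match(colnames(betas), samples$sample_id)
  if (anyNA(idx)) stop_wkde("samples missing from the sample table: ",
                            paste(colnames(betas)[is.na(idx)][1:3], collapse = ", "))
  ages <- samples$age[idx]
  r <- suppressWarnings(as.vector(stats::cor(t(betas), ages,
                                             use = "pairwise.complete.obs")))
  r2 <- r^2
  n_ok <- rowSums(!is.na(betas))
  r2[n_ok < min_n | (1 - n_ok / ncol(betas)) > max_missing_frac] <- NA_real_
  names(r2) <- rownames(betas)
  r2
}

#' Select the clock signature
#'
#' Keeps CpGs whose squared age correlation strictly exceeds `threshold`,
#' ordered by descending r-squared with ties broken lexicographically by
#' CpG id -- deterministic regardless of input order.
#'
#' @param r2 Named vector from [age_correlation()] (`NA`s ignored).
#' @param threshold Strict lower bound in \[0, 1).
#' @return Ordered character vector of CpG ids.
#' @examples
#' select_signature(c(a = 0.9, b = 0.71, c = 0.65), threshold = 0.7)
#' @export
select_signature <- function(r2, threshold = 0.7) {
  stopifnot(is.numeric(threshold), threshold >= 0, threshold < 1)
  r2 <- r2[!is.na(r2)]
  keep <- r2 > threshold
  if (!any(keep))
    stop_wkde("no CpG exceeds r^2 > ", threshold,
              "; consider a lower threshold")
  r2 <- r2[keep]
  names(r2)[order(-r2, names(r2))]
}

#' Uniform-age subsampling of a training set
#'
#' Splits samples into 5-year age bins from 0 to 90 years plus one overflow
#' bin for ages strictly above 90 (age exactly 90 falls in the last regular
#' bin), then draws `per_bin` samples per bin without replacement. Bins
#' holding fewer than `per_bin` samples contribute everything they have
#' ("take-all"); empty bins contribute nothing, with a warning. With the
#' defaults and all 19 bins full the subset holds 19 x 15 = 285 samples.
#'
#' @param samples Sample table with `age` in years.
#' @param bin_width Bin width in years.
#' @param regular_max Upper edge of the regular bins (years).
#' @param per_bin Samples drawn per bin.
#' @param seed Optional seed for the draw (restores the RNG state after use).
#' @return The subsampled rows of `samples`, in their original order.
#' @export
uniform_age_subsample <- function(samples, bin_width = 5, regular_max = 90,
                                  per_bin = 15, seed = NULL) {
  stopifnot(bin_width > 0, per_bin >= 1, all(samples$age >= 0))
  n_regular <- as.integer(regular_max / bin_width)
  bin <- ifelse(samples$age > regular_max, n_regular,
                pmin(floor(samples$age / bin_width), n_regular - 1L))
  chosen <- with_seed(seed, {
    unlist(lapply(0:n_regular, function(b) {
      ids <- samples$sample_id[bin == b]
      if (length(ids) == 0) {
        warning(sprintf("age bin %d is empty", b + 1L), call. = FALSE)
        return(character(0))
      }
      if (length(ids) <= per_bin) {
        if (length(ids) < per_bin)
          wkde_log(sprintf("age bin %d holds only %d samples; taking all",
                           b + 1L, length(ids)))
        return(ids)
      }
      sample(ids, per_bin)
    }), use.names = FALSE)
  })
  samples[samples$sample_id %in% chosen, , drop = FALSE]
}
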