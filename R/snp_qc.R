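#' Call rate of a marker
#'
#' Fraction of individuals with a non-missing genotype call.
#'
#' @param x Integer/numeric vector of dosages (0/1/2/NA) for one marker.
#' @return Proportion in [0, 1].
#' @export
call_rate <- function(x) {
  if (length(x) == 0) stop("empty marker column", call. = FALSE)
  mean(!is.na(x))
}

#' Minor allele frequency of a biallelic marker
#'
#' Computed on non-missing calls only: with p the frequency of the counted
#' allele, \code{p = (2 n2 + n1) / (2 n)}, MAF = min(p, 1 - p).
#'
#' @param x Dosage vector (0/1/2/NA).
#' @return Proportion in [0, 0.5].
#' @export
minor_allele_frequency <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("MAF undefined: all calls missing", call. = FALSE)
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

#' Critical (minimum detectable) minor allele frequency
#'
#' The frequency of an allele seen exactly once in N diploid individuals,
#' \code{1 / (2 N)} — the lowest MAF observable in the sample. Advisory
#' only; the default QC filter uses the conventional 5\% threshold.
#'
#' @param n_individuals Number of genotyped individuals.
#' @return \code{1 / (2 * n_individuals)}.
#' @export
maf_critical_level <- function(n_individuals) {
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  1 / (2 * n_individuals)
}

#' Is a marker invariant (no genetic variance)?
#'
#' TRUE when every non-missing call is the same genotype — including
#' heterozygous-in-everyone, the signature of a spurious polymorphism
#' between homeologous subgenome copies in an allopolyploid.
#'
#' @param x Dosage vector (0/1/2/NA).
#' @return Logical.
#' @export
is_invariant <- function(x) {
  x <- x[!is.na(x)]
  length(unique(x)) <= 1
}

#' Percent reduction of a marker panel
#'
#' @param n_input,n_retained Marker counts before and after filtering.
#' @return \code{100 * (n_input - n_retained) / n_input}.
#' @export
reduction_percent <- function(n_input, n_retained) {
  if (any(n_input <= 0)) stop("n_input must be positive", call. = FALSE)
  100 * (n_input - n_retained) / n_input
}

#' Quality control of a SNP panel
#'
#' Retains markers with call rate and MAF at or above the thresholds
#' (inclusive) and with genetic variance among individuals. Each removed
#' marker is attributed to the first filter it fails, in the fixed order
#' call rate, MAF, invariance, so removal counts are reproducible; the
#' retained set itself does not depend on this order.
#'
#' @param panel A \code{marker_panel}.
#' @param cr_threshold Minimum call rate (default 0.90).
#' @param maf_threshold Minimum minor allele frequency (default 0.05).
#' @return List with \code{panel} (the filtered \code{marker_panel}) and
#'   \code{report} (a \code{qc_report}: input/retained/removed counts,
#'   \code{reduction_percent}, and a per-chromosome table).
#' @export
run_qc <- function(panel, cr_threshold = 0.90, maf_threshold = 0.05) {
  stopifnot(inherits(panel, "marker_panel"))
  G <- panel$genotypes
  if (ncol(G) == 0) stop("empty marker panel", call. = FALSE)

  cr <- apply(G, 2, call_rate)
  maf <- apply(G, 2, function(x)
    if (all(is.na(x))) 0 else minor_allele_frequency(x))
  inv <- apply(G, 2, is_invariant)

  fail_cr <- cr < cr_threshold
  fail_maf <- !fail_cr & maf < maf_threshold
  fail_inv <- !fail_cr & !fail_maf & inv
  keep <- !(fail_cr | fail_maf | fail_inv)

  per_chr <- do.call(rbind, lapply(split(seq_len(ncol(G)), panel$map$chromosome),
    function(idx) data.frame(n_input = length(idx),
                             n_retained = sum(keep[idx]))))
  per_chr <- data.frame(chromosome = rownames(per_chr), per_chr,
                        row.names = NULL, stringsAsFactors = FALSE)
  per_chr$reduction_percent <- reduction_percent(per_chr$n_input,
                                                 per_chr$n_retained)

  report <- structure(list(
    n_input = ncol(G),
    n_retained = sum(keep),
    n_removed_callrate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_invariant = sum(fail_inv),
    reduction_percent = reduction_percent(ncol(G), sum(keep)),
    cr_threshold = cr_threshold, maf_threshold = maf_threshold,
    per_chromosome = per_chr), class = "qc_report")

  out <- structure(list(genotypes = G[, keep, drop = FALSE],
                        map = panel$map[keep, , drop = FALSE],
                        invariant_markers = intersect(panel$invariant_markers,
                                                      colnames(G)[keep])),
                   class = "marker_panel")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("SNP quality control: %d markers in, %d retained (%.2f%% removed)\n",
              x$n_input, x$n_retained, x$reduction_percent))
  cat(sprintf("  removed: %d call rate < %.2f, %d MAF < %.3f, %d invariant\n",
              x$n_removed_callrate, x$cr_threshold,
              x$n_removed_maf, x$maf_threshold, x$n_removed_invariant))
  print(x$per_chromosome, row.names = FALSE)
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A \code{qc_report}.
#' @param path Output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
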