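#' Default PLINK-style ROH scan parameters
#'
#' The three flags named in the study (window/segment SNP count 50, minimum
#' segment 1000 kb, maximum gap 1000 kb) plus the documented PLINK 1.9
#' defaults for the unnamed ones.
#'
#' @return Named list of parameters.
#' @export
roh_params <- function(window_snp = 50, min_kb = 1000, max_gap_kb = 1000,
                       window_het = 1, window_missing = 5,
                       hit_threshold = 0.05, density_kb_per_snp = 50) {
  list(window_snp = as.integer(window_snp), min_kb = min_kb,
       max_gap_kb = max_gap_kb, window_het = as.integer(window_het),
       window_missing = as.integer(window_missing),
       hit_threshold = hit_threshold,
       density_kb_per_snp = density_kb_per_snp)
}

#' Call runs of homozygosity for one individual (PLINK-style scan)
#'
#' Slides a `window_snp`-SNP window along each scaffold; a window is
#' homozygous when it contains at most `window_het` heterozygous and at most
#' `window_missing` missing calls. Each SNP's hit rate is the fraction of
#' windows containing it that are homozygous; SNPs with hit rate >=
#' `hit_threshold` qualify. Consecutive qualifying SNPs are joined unless
#' their gap exceeds `max_gap_kb`; segments are emitted when they hold at
#' least `window_snp` SNPs, span at least `min_kb`, and have density at most
#' `density_kb_per_snp` kb per SNP.
#'
#' @param genotype Integer vector of minor-allele dose (0/1/2; NA = missing)
#'   for one individual.
#' @param scaffold,pos Site coordinates (1-based, sorted within scaffold).
#' @param params A [roh_params()] list.
#' @return Data frame of class `roh_segments`: scaffold, start, end, n_snps,
#'   length (= end - start + 1).
#' @export
call_roh <- function(genotype, scaffold, pos, params = roh_params()) {
  stopifnot(length(genotype) == length(pos), length(scaffold) == length(pos))
  segs <- list()
  for (sc in unique(scaffold)) {
    sel <- scaffold == sc
    p <- pos[sel]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing within scaffold ", sc)
    }
    g <- genotype[sel]
    segs[[sc]] <- roh_scan_scaffold(g, p, params, sc)
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_snps = integer(), length = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

roh_scan_scaffold <- function(g, pos, prm, sc) {
  n <- length(g)
  w <- prm$window_snp
  if (n < w) return(NULL)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  n_win <- n - w + 1L
  j <- seq_len(n_win)
  hom_win <- (ch[j + w] - ch[j]) <= prm$window_het &
             (cm[j + w] - cm[j]) <= prm$window_missing
  # hit rate per SNP i over windows starting in [i - w + 1, i] clipped to range
  cw <- c(0L, cumsum(as.integer(hom_win)))
  i <- seq_len(n)
  first <- pmax(1L, i - w + 1L)
  last <- pmin(i, n_win)
  n_cover <- pmax(0L, last - first + 1L)
  hits <- ifelse(n_cover > 0L, cw[last + 1L] - cw[first], 0L)
  rate <- ifelse(n_cover > 0L, hits / n_cover, 0)
  qual <- rate >= prm$hit_threshold & n_cover > 0L

  # join consecutive qualifying SNPs, breaking at gaps > max_gap_kb
  idx <- which(qual)
  if (!length(idx)) return(NULL)
  brk <- c(TRUE, diff(idx) > 1L |
                 diff(pos[idx]) > prm$max_gap_kb * 1000)
  run <- cumsum(brk)
  out <- do.call(rbind, lapply(split(idx, run), function(ii) {
    data.frame(scaffold = sc, start = pos[ii[1]], end = pos[ii[length(ii)]],
               n_snps = length(ii),
               length = pos[ii[length(ii)]] - pos[ii[1]] + 1,
               stringsAsFactors = FALSE)
  }))
  keep <- out$n_snps >= w &
          out$length >= prm$min_kb * 1000 &
          (out$length / 1000) / out$n_snps <= prm$density_kb_per_snp
  out <- out[keep, , drop = FALSE]
  if (!nrow(out)) NULL else out
}

#' Call ROH for every individual of a genotype object
#'
#' @param geno An `erosion_geno` (or a list with `geno` matrix and `sites`).
#' @param params A [roh_params()] list.
#' @return Data frame with an `id` column prepended to the per-individual
#'   segments.
#' @export
call_roh_all <- function(geno, params = roh_params()) {
  stopifnot(inherits(geno, "erosion_geno"))
  out <- lapply(geno$individuals$id, function(id) {
    s <- call_roh(geno$geno[id, ], geno$sites$scaffold, geno$sites$pos, params)
    if (nrow(s)) cbind(id = id, s) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient FROH from ROH segments
#'
#' FROH = (summed length of segments exceeding `min_segment` that lie on
#' qualifying scaffolds) / (summed length of scaffolds exceeding
#' `min_scaffold`).
#'
#' @param segments ROH segment data frame (scaffold, start, end, length).
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param min_scaffold Scaffolds must exceed this length to enter the
#'   denominator (default 10 Mb).
#' @param min_segment Segments must exceed this length to enter the numerator
#'   (default 1 Mb).
#' @return List of class `froh_profile`: `froh`, per-class FROH over the
#'   standard length classes, `denominator_bp`, `n_segments`.
#' @export
compute_froh <- function(segments, scaffold_lengths,
                         min_scaffold = 10e6, min_segment = 1e6) {
  qual_scaf <- names(scaffold_lengths)[scaffold_lengths > min_scaffold]
  if (!length(qual_scaf)) stop("no scaffold exceeds the minimum length")
  denom <- sum(scaffold_lengths[qual_scaf])
  on_qual <- segments[segments$scaffold %in% qual_scaf, , drop = FALSE]
  num_segs <- on_qual[on_qual$length > min_segment, , drop = FALSE]
  classes <- bin_roh_classes(on_qual)
  structure(list(
    froh = sum(num_segs$length) / denom,
    froh_by_class = classes$length_bp / denom,
    class_counts = classes$count,
    denominator_bp = denom,
    n_segments = nrow(num_segs)
  ), class = "froh_profile")
}

#' Bin ROH segments into the five standard length classes
#'
#' Classes (Mb): \[0.5, 1), \[1, 2), \[2, 5), \[5, 10), \[10, Inf) -
#' half-open, lower-inclusive. Segments shorter than 0.5 Mb are not binned.
#'
#' @param segments ROH segment data frame with a `length` column (bp).
#' @return List with named `count` and `length_bp` vectors per class.
#' @export
bin_roh_classes <- function(segments) {
  breaks <- c(0.5e6, 1e6, 2e6, 5e6, 10e6, Inf)
  labels <- c("0.5-1", "1-2", "2-5", "5-10", ">10")
  cls <- cut(segments$length, breaks = breaks, labels = labels,
             right = FALSE, include.lowest = FALSE)
  count <- table(factor(cls, levels = labels))
  length_bp <- tapply(segments$length, factor(cls, levels = labels), sum,
                      default = 0)
  list(count = stats::setNames(as.integer(count), labels),
       length_bp = stats::setNames(as.numeric(length_bp), labels))
}

#' Map ROH length to the age of the inbreeding event
#'
#' Under recombination rate r (cM/Mb), an autozygous tract of length L Mb
#' reflects a common ancestor g generations back. Two conventions are
#' implemented: `"stated"` uses g = 100/(2rL); `"as_applied"` (default) uses
#' g = 100/(rL), which reproduces the conventional class-to-generation
#' values (0.5 Mb -> 200 generations, 1 -> 100, 2 -> 50, 5 -> 20, 10 -> 10).
#' The two differ by the factor 2; they are never blended.
#'
#' @param length_mb ROH length in Mb (> 0).
#' @param r Recombination rate in cM/Mb (default 1).
#' @param generation_time Years per generation (default 6).
#' @param convention `"as_applied"` (default) or `"stated"`.
#' @return Data frame with `length_mb`, `generations`, `years`.
#' @export
roh_age <- function(length_mb, r = 1, generation_time = 6,
                    convention = c("as_applied", "stated")) {
  convention <- match.arg(convention)
  if (any(length_mb <= 0)) stop("length must be positive")
  if (r <= 0) stop("recombination rate must be positive")
  g <- switch(convention,
              as_applied = 100 / (r * length_mb),
              stated = 100 / (2 * r * length_mb))
  data.frame(length_mb = length_mb, generations = g,
             years = g * generation_time)
}
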