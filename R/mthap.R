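#' Collapse an aligned mitochondrial FASTA into haplotypes
#'
#' Alignment columns in which more than `max_col_missing` of sequences carry
#' a gap or N are masked; sequences still containing missing characters
#' after masking are excluded (and reported); the remaining identical
#' sequences are collapsed into haplotypes. Sequence names may carry
#' `id|epoch=historic|pop=QLD`-style tags, which are parsed into the
#' assignment table.
#'
#' @param sequences Named character vector of equal-length aligned sequences,
#'   or a path to a FASTA file ([read_labelled_fasta()] is used).
#' @param max_col_missing Maximum tolerated missing fraction per column
#'   (default 0.2).
#' @return Object of class `haplotype_table`: `alignment_length`,
#'   `masked_columns`, `haplotypes` (id -> collapsed sequence),
#'   `assignments` (id, epoch, pop, haplotype), `counts`, `n`, `p`,
#'   `excluded` ids.
#' @export
call_haplotypes <- function(sequences, max_col_missing = 0.2) {
  if (is.character(sequences) && length(sequences) == 1 &&
      !grepl("^[ACGTUNacgtun?-]+$", sequences)) {
    if (!file.exists(sequences)) stop("no such FASTA file: ", sequences)
    sequences <- read_labelled_fasta(sequences)
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("sequences must be equal length")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(sequences, ""))
  missing <- mat == "N" | mat == "-" | mat == "?"
  masked <- which(colMeans(missing) > max_col_missing)
  keep_cols <- setdiff(seq_len(L), masked)
  mat2 <- mat[, keep_cols, drop = FALSE]
  still_missing <- rowSums(mat2 == "N" | mat2 == "-" | mat2 == "?") > 0
  labels <- parse_seq_labels(names(sequences))
  excluded <- labels$id[still_missing]
  mat2 <- mat2[!still_missing, , drop = FALSE]
  labels <- labels[!still_missing, , drop = FALSE]
  if (!nrow(mat2)) stop("no sequences left after missing-data exclusion")
  seqs <- apply(mat2, 1, paste, collapse = "")
  uniq <- unique(seqs)
  hap_ids <- sprintf("H%02d", seq_along(uniq))
  labels$haplotype <- hap_ids[match(seqs, uniq)]
  counts <- table(factor(labels$haplotype, levels = hap_ids))
  structure(list(
    alignment_length = L,
    masked_columns = masked,
    haplotypes = stats::setNames(uniq, hap_ids),
    assignments = labels,
    counts = stats::setNames(as.integer(counts), hap_ids),
    n = nrow(labels),
    p = as.numeric(counts) / nrow(labels),
    excluded = excluded
  ), class = "haplotype_table")
}

parse_seq_labels <- function(nm) {
  if (is.null(nm)) nm <- sprintf("seq%03d", seq_along(nm))
  parts <- strsplit(nm, "|", fixed = TRUE)
  get_tag <- function(p, tag) {
    hit <- grep(paste0("^", tag, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", tag, "="), "", hit[1]) else NA_character_
  }
  data.frame(
    id = vapply(parts, `[`, "", 1),
    epoch = vapply(parts, get_tag, "", tag = "epoch"),
    pop = vapply(parts, get_tag, "", tag = "pop"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes over", x$n,
      "individuals (", length(x$masked_columns), "columns masked,",
      length(x$excluded), "sequences excluded )\n")
  invisible(x)
}

#' Haplotype (gene) diversity with small-sample correction
#'
#' Hd = n/(n-1) (1 - sum p_i^2), the probability that two randomly drawn
#' haplotypes differ (Nei's gene diversity).
#'
#' @param x A `haplotype_table`, a vector of per-individual haplotype labels,
#'   or a count vector.
#' @param counts If TRUE, treat `x` as haplotype counts.
#' @return Hd in \[0, 1\].
#' @export
haplotype_diversity <- function(x, counts = FALSE) {
  k <- if (inherits(x, "haplotype_table")) {
    x$counts
  } else if (counts) {
    as.numeric(x)
  } else {
    as.numeric(table(x))
  }
  n <- sum(k)
  if (n < 2) stop("need at least two individuals")
  p <- k / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Permutation test for a haplotype-diversity difference between epochs
#'
#' The observed statistic is delta Hd = Hd_A - Hd_B. Epoch labels are
#' permuted among the pooled individuals, preserving group sizes; the
#' p-value uses the add-one convention p = (1 + #extreme) / (1 + permutations)
#' with extremeness |delta*| >= |delta| for the two-sided default, or
#' delta* >= delta ("greater") / delta* <= delta ("less").
#'
#' @param hapA,hapB Per-individual haplotype label vectors for the two
#'   groups (e.g. from a `haplotype_table`'s assignments split by epoch), or
#'   two `haplotype_table`s.
#' @param n_permutations Number of permutations (default 10000; < 100 warns,
#'   < 1 errors).
#' @param seed Integer seed.
#' @param sidedness `"two"` (default), `"greater"`, `"less"`.
#' @return List of class `permutation_result`: `observed`, `null` sample,
#'   `p_value`, `n_permutations`, `seed`, `sidedness`.
#' @export
permutation_test_hd <- function(hapA, hapB, n_permutations = 10000,
                                seed = 1L, sidedness = c("two", "greater",
                                                         "less")) {
  sidedness <- match.arg(sidedness)
  if (inherits(hapA, "haplotype_table")) hapA <- hapA$assignments$haplotype
  if (inherits(hapB, "haplotype_table")) hapB <- hapB$assignments$haplotype
  nA <- length(hapA); nB <- length(hapB)
  if (nA < 2 || nB < 2) stop("both groups need n >= 2")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (n_permutations < 100) warning("fewer than 100 permutations")
  obs <- haplotype_diversity(hapA) - haplotype_diversity(hapB)
  pool <- c(hapA, hapB)
  withr::with_seed(as.integer(seed), {
    null <- vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(nA + nB, nA)
      haplotype_diversity(pool[idx]) - haplotype_diversity(pool[-idx])
    }, numeric(1))
  })
  eps <- 1e-12
  extreme <- switch(sidedness,
    two = abs(null) >= abs(obs) - eps,
    greater = null >= obs - eps,
    less = null <= obs + eps)
  structure(list(
    observed = obs,
    null = null,
    p_value = (1 + sum(extreme)) / (1 + n_permutations),
    n_permutations = n_permutations,
    seed = as.integer(seed),
    sidedness = sidedness
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed delta Hd = %.4f, p = %.4g (%s-sided, %d permutations)\n",
    x$observed, x$p_value, x$sidedness, x$n_permutations))
  invisible(x)
}
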