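BASES <- c("A", "C", "G", "T")

#' Simulate two-epoch diploid genotypes with known ground truth
#'
#' Sites are independent (no linkage). Ancestral (historic) minor allele
#' frequencies are drawn from a neutral-like folded SFS with density
#' proportional to 1/x truncated to \[1/two_n, 1 - 1/two_n\]; a site is
#' polymorphic with the probability that makes the expected per-site
#' heterozygosity equal `theta`. Contemporary frequencies are obtained from
#' historic ones by binomial drift through an effective number of founder
#' allele copies chosen so that expected heterozygosity is multiplied by
#' `bottleneck_factor` exactly.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `erosion_geno`: genotype matrix (individuals x
#'   sites, minor-allele dose 0/1/2), site table (scaffold, pos, ref, alt,
#'   historic and contemporary allele frequencies), individual table
#'   (id, epoch), scaffold lengths, and a `truth` list with per-individual
#'   realized heterozygosity, FROH (0 until [plant_roh()] is used) and
#'   planted-tract table.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n_ind <- cfg$n_historic + cfg$n_contemporary
    S <- cfg$n_sites

    # site placement: spread sites across scaffolds, distinct sorted positions
    per_scaf <- diff(round(seq(0, S, length.out = cfg$n_scaffolds + 1)))
    scaffold <- rep(sprintf("scaf%03d", seq_len(cfg$n_scaffolds)), per_scaf)
    pos <- unlist(lapply(per_scaf, function(k) {
      sort(sample.int(cfg$scaffold_length, k))
    }), use.names = FALSE)

    # truncated 1/x SFS by inverse CDF
    lo <- 1 / cfg$two_n
    hi <- 1 - lo
    x <- lo * (hi / lo)^stats::runif(S)
    e_het_sfs <- 2 * ((hi - lo) - (hi^2 - lo^2) / 2) / log(hi / lo)
    p_poly <- min(1, cfg$theta / e_het_sfs)
    poly <- stats::runif(S) < p_poly
    p_hist <- ifelse(poly, x, 0)

    p_cont <- drift_frequencies(p_hist, cfg$bottleneck_factor)

    ref <- sample(BASES, S, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")

    epoch <- c(rep("historic", cfg$n_historic),
               rep("contemporary", cfg$n_contemporary))
    ids <- sprintf("%s%03d", ifelse(epoch == "historic", "HIS", "CON"),
                   unlist(lapply(table(factor(epoch, c("historic", "contemporary"))), seq_len)))
    p_by_ind <- rbind(
      matrix(rep(p_hist, each = cfg$n_historic), cfg$n_historic, S),
      matrix(rep(p_cont, each = cfg$n_contemporary), cfg$n_contemporary, S)
    )
    geno <- matrix(stats::rbinom(n_ind * S, 2L, p_by_ind), n_ind, S)
    rownames(geno) <- ids

    scaffold_lengths <- stats::setNames(
      rep(cfg$scaffold_length, cfg$n_scaffolds),
      sprintf("scaf%03d", seq_len(cfg$n_scaffolds))
    )

    obj <- structure(list(
      geno = geno,
      sites = data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
                         p_historic = p_hist, p_contemporary = p_cont,
                         stringsAsFactors = FALSE),
      individuals = data.frame(id = ids, epoch = epoch,
                               stringsAsFactors = FALSE),
      scaffold_lengths = scaffold_lengths,
      cfg = cfg,
      truth = list()
    ), class = "erosion_geno")
    obj$truth <- list(
      het = rowMeans(geno == 1L),
      froh = stats::setNames(rep(0, n_ind), ids),
      tracts = data.frame(id = character(), scaffold = character(),
                          start = numeric(), end = numeric(),
                          length = numeric(), stringsAsFactors = FALSE)
    )
    obj
  })
}

# Binomial drift producing E[2p'(1-p')] = b * 2p(1-p) exactly:
# resample through n founder allele copies, where n is a randomized rounding
# of 1/(1-b) so that E[1 - 1/n] = b.
drift_frequencies <- function(p, b) {
  if (b == 1) return(p)
  S <- length(p)
  target <- 1 / (1 - b)
  n0 <- max(1L, floor(target))
  n1 <- n0 + 1L
  f0 <- 1 - 1 / n0
  f1 <- 1 - 1 / n1
  w1 <- (b - f0) / (f1 - f0)      # P(use n1)
  n <- ifelse(stats::runif(S) < w1, n1, n0)
  stats::rbinom(S, n, p) / n
}

#' Plant autozygous tracts (runs of homozygosity) with a target FROH
#'
#' Non-overlapping tracts with lengths drawn from the standard ROH length
#' classes are placed uniformly on the scaffolds of each individual until the
#' summed tract length reaches `froh_target` of the genome (the last tract is
#' truncated to land within the class range when possible). Every site inside
#' a tract is forced homozygous, the single tract haplotype allele drawn from
#' the site's epoch allele frequency.
#'
#' @param geno An `erosion_geno` object.
#' @param froh_target Fraction of the genome to cover, in \[0, 1).
#' @param length_class_mix Named probability vector over the length classes
#'   `c("0.5-1", "1-2", "2-5", "5-10", ">10")` (Mb).
#' @param seed Integer seed.
#' @param individuals Ids to plant in (default all).
#' @return The modified `erosion_geno` with updated truth (FROH, tract table,
#'   recomputed heterozygosity).
#' @export
plant_roh <- function(geno, froh_target,
                      length_class_mix = c("0.5-1" = .2, "1-2" = .3,
                                           "2-5" = .3, "5-10" = .15,
                                           ">10" = .05),
                      seed = 1L, individuals = NULL) {
  stopifnot(inherits(geno, "erosion_geno"))
  if (froh_target < 0 || froh_target >= 1) stop("froh_target must be in [0, 1)")
  if (froh_target == 0) return(geno)
  class_lo <- c(0.5e6, 1e6, 2e6, 5e6, 10e6)
  class_hi <- c(1e6, 2e6, 5e6, 10e6, 20e6)
  mix <- length_class_mix / sum(length_class_mix)
  total_bp <- sum(geno$scaffold_lengths)
  max_len <- max(geno$scaffold_lengths)
  if (max_len < min(class_lo)) stop("scaffolds too short for any ROH class")
  if (froh_target > 0.85) stop("froh_target infeasible for scaffold length")
  if (is.null(individuals)) individuals <- geno$individuals$id

  withr::with_seed(as.integer(seed), {
    freq_col <- ifelse(
      geno$individuals$epoch[match(individuals, geno$individuals$id)] == "historic",
      "p_historic", "p_contemporary")
    tracts <- list()
    for (k in seq_along(individuals)) {
      id <- individuals[k]
      target_bp <- froh_target * total_bp
      placed <- data.frame(scaffold = character(), start = numeric(),
                           end = numeric())
      cum <- 0
      tries <- 0
      while (cum < target_bp && tries < 2000) {
        tries <- tries + 1
        cl <- sample.int(5L, 1L, prob = mix)
        len <- round(stats::runif(1, class_lo[cl], min(class_hi[cl], max_len)))
        remaining <- target_bp - cum
        if (len > remaining) {
          # truncate the final tract into range if a class admits it
          if (remaining >= min(class_lo)) len <- round(remaining) else break
        }
        scaf <- sample(names(geno$scaffold_lengths), 1L,
                       prob = geno$scaffold_lengths)
        L <- geno$scaffold_lengths[[scaf]]
        if (len > L) next
        start <- sample.int(L - len + 1L, 1L)
        end <- start + len - 1
        same <- placed[placed$scaffold == scaf, , drop = FALSE]
        if (nrow(same) && any(start <= same$end & end >= same$start)) next
        placed <- rbind(placed, data.frame(scaffold = scaf, start = start,
                                           end = end))
        cum <- cum + len
      }
      if (cum < target_bp * 0.9) {
        stop("froh_target infeasible for scaffold length (placed ",
             signif(cum / total_bp, 3), " of genome)")
      }
      # force homozygosity inside tracts
      for (j in seq_len(nrow(placed))) {
        idx <- which(geno$sites$scaffold == placed$scaffold[j] &
                     geno$sites$pos >= placed$start[j] &
                     geno$sites$pos <= placed$end[j])
        if (length(idx)) {
          p <- geno$sites[[freq_col[k]]][idx]
          geno$geno[id, idx] <- 2L * stats::rbinom(length(idx), 1L, p)
        }
      }
      placed$id <- id
      placed$length <- placed$end - placed$start + 1
      tracts[[k]] <- placed
    }
    tracts <- do.call(rbind, tracts)
    geno$truth$tracts <- rbind(geno$truth$tracts,
                               tracts[, c("id", "scaffold", "start", "end",
                                          "length")])
    froh <- tapply(geno$truth$tracts$length, geno$truth$tracts$id, sum) / total_bp
    geno$truth$froh[names(froh)] <- froh
    geno$truth$het <- rowMeans(geno$geno == 1L)
    geno
  })
}

# 4x4 base emission matrix: damage (C->T, G->A with prob dmg on the true
# base), then uniform sequencing error among the three other bases.
base_emission_matrix <- function(error_rate, damage_rate) {
  D <- diag(4)
  dimnames(D) <- list(BASES, BASES)
  D["C", "C"] <- 1 - damage_rate; D["C", "T"] <- damage_rate
  D["G", "G"] <- 1 - damage_rate; D["G", "A"] <- damage_rate
  E <- matrix(error_rate / 3, 4, 4, dimnames = list(BASES, BASES))
  diag(E) <- 1 - error_rate
  D %*% E
}

#' Simulate read pileups over simulated genotypes
#'
#' Per-site read depth is Poisson(coverage); each read samples one of the two
#' genotype alleles uniformly, is damaged (true C emitted as T, true G as A,
#' strand-collapsed) with probability `damage_rate`, then flipped to one of
#' the three other bases with probability `error_rate` (uniform among them).
#' Base qualities are the Phred equivalent of `error_rate`.
#'
#' @param geno An `erosion_geno` object.
#' @param coverage Scalar mean depth, or named vector per individual id, or
#'   NULL to use the config's epoch coverages.
#' @param error_rate,damage_rate Per-read probabilities; default from config.
#' @param seed Integer seed.
#' @return An `erosion_pileup`: base-count array (sites x individuals x ACGT)
#'   with site coordinates and the constant Phred quality.
#' @export
simulate_reads <- function(geno, coverage = NULL, error_rate = NULL,
                           damage_rate = NULL, seed = 1L) {
  stopifnot(inherits(geno, "erosion_geno"))
  cfg <- geno$cfg
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  if (is.null(damage_rate)) damage_rate <- cfg$damage_rate
  if (error_rate < 0 || damage_rate < 0) stop("rates must be non-negative")
  n_ind <- nrow(geno$individuals)
  S <- nrow(geno$sites)
  if (is.null(coverage)) {
    coverage <- ifelse(geno$individuals$epoch == "historic",
                       cfg$coverage_historic, cfg$coverage_contemporary)
  } else if (length(coverage) == 1L) {
    coverage <- rep(coverage, n_ind)
  } else {
    coverage <- coverage[geno$individuals$id]
  }
  if (any(coverage < 0)) stop("coverage must be non-negative")
  dmg <- ifelse(geno$individuals$epoch == "historic", damage_rate, 0)

  withr::with_seed(as.integer(seed), {
    counts <- array(0L, c(S, n_ind, 4L),
                    dimnames = list(NULL, geno$individuals$id, BASES))
    ref_code <- match(geno$sites$ref, BASES)
    alt_code <- match(geno$sites$alt, BASES)
    for (i in seq_len(n_ind)) {
      d <- stats::rpois(S, coverage[i])
      g <- geno$geno[i, ]
      # reads from the "alt" haplotype: all (g==2), none (g==0), Binom(d,1/2) het
      d_alt <- integer(S)
      het <- g == 1L
      d_alt[het] <- stats::rbinom(sum(het), d[het], 0.5)
      d_alt[g == 2L] <- d[g == 2L]
      d_ref <- d - d_alt
      M <- base_emission_matrix(error_rate, dmg[i])
      counts[, i, ] <- counts[, i, ] +
        emit_base_counts(d_ref, ref_code, M) +
        emit_base_counts(d_alt, alt_code, M)
    }
    structure(list(
      scaffold = geno$sites$scaffold,
      pos = geno$sites$pos,
      counts = counts,
      qual = if (error_rate > 0) -10 * log10(error_rate) else 93,
      individuals = geno$individuals
    ), class = "erosion_pileup")
  })
}

# Vectorized multinomial emission: n[s] reads of source allele src[s] emitted
# through row M[src, ] of the emission matrix, via sequential binomials.
emit_base_counts <- function(n, src, M) {
  S <- length(n)
  out <- matrix(0L, S, 4L)
  for (a in 1:4) {
    idx <- which(src == a & n > 0L)
    if (!length(idx)) next
    p <- M[a, ]
    rem <- n[idx]
    pleft <- 1
    for (b in 1:3) {
      pr <- if (pleft <= 0) 0 else min(1, p[b] / pleft)
      x <- stats::rbinom(length(idx), rem, pr)
      out[idx, b] <- x
      rem <- rem - x
      pleft <- pleft - p[b]
    }
    out[idx, 4] <- rem
  }
  out
}

#' Simulate labelled mitochondrial haplotype alignments for two epochs
#'
#' Haplotype sequences are generated on a random coalescent genealogy
#' ([ape::rcoal()]) with Poisson numbers of mutations per branch; duplicated
#' sequences receive extra private mutations so haplotypes are distinct.
#' Historic haplotype frequencies are Dirichlet(1); the contemporary epoch
#' either draws an independent Dirichlet vector (`drop_rare = 0`) or reuses
#' the historic vector with its `drop_rare` rarest haplotypes removed and
#' renormalized, emulating lost rare matrilines.
#'
#' @param cfg A [sim_config()] (provides epoch sample sizes and seed).
#' @param n_haplotypes Number of distinct source haplotypes.
#' @param seq_length Alignment length in bp.
#' @param seed Integer seed (default the config seed).
#' @param drop_rare How many of the rarest historic haplotypes are absent from
#'   the contemporary epoch.
#' @param mut_rate Per-site mutation rate per unit coalescent branch length.
#' @return List with `sequences` (named character vector, names carrying
#'   `id|epoch=...|pop=SIM` tags), `assignments` data frame, and `truth`
#'   (per-epoch haplotype frequency vectors and source haplotype sequences).
#' @export
simulate_mt_haplotypes <- function(cfg, n_haplotypes = 5, seq_length = 500,
                                   seed = NULL, drop_rare = 0,
                                   mut_rate = 0.005) {
  stopifnot(inherits(cfg, "sim_config"), n_haplotypes >= 1)
  if (seq_length < 1) stop("seq_length must be strictly positive")
  if (is.null(seed)) seed <- cfg$seed
  withr::with_seed(as.integer(seed), {
    K <- as.integer(n_haplotypes)
    anc <- sample(BASES, seq_length, replace = TRUE)
    haps <- matrix(rep(anc, K), nrow = K, byrow = TRUE)
    if (K > 1) {
      tr <- ape::rcoal(K)
      # propagate mutations from root to tips
      seqs <- vector("list", max(tr$edge))
      root <- K + 1L
      seqs[[root]] <- anc
      ord <- ape::reorder.phylo(tr, "cladewise")
      for (j in seq_len(nrow(ord$edge))) {
        par <- ord$edge[j, 1]; child <- ord$edge[j, 2]
        s <- seqs[[par]]
        nm <- stats::rpois(1, ord$edge.length[j] * mut_rate * seq_length)
        if (nm > 0) {
          at <- sample.int(seq_length, min(nm, seq_length))
          s[at] <- vapply(s[at], function(b) sample(setdiff(BASES, b), 1L), "")
        }
        seqs[[child]] <- s
      }
      for (k in seq_len(K)) haps[k, ] <- seqs[[k]]
    }
    # enforce distinctness with private mutations
    key <- apply(haps, 1, paste, collapse = "")
    guard <- 0
    while (anyDuplicated(key) && guard < 100) {
      guard <- guard + 1
      for (k in which(duplicated(key))) {
        at <- sample.int(seq_length, 1L)
        haps[k, at] <- sample(setdiff(BASES, haps[k, at]), 1L)
      }
      key <- apply(haps, 1, paste, collapse = "")
    }

    f_hist <- as.vector(stats::rgamma(K, 1)); f_hist <- f_hist / sum(f_hist)
    if (drop_rare > 0 && K > drop_rare) {
      f_cont <- f_hist
      f_cont[order(f_hist)[seq_len(drop_rare)]] <- 0
      f_cont <- f_cont / sum(f_cont)
    } else {
      f_cont <- as.vector(stats::rgamma(K, 1)); f_cont <- f_cont / sum(f_cont)
    }

    draw <- function(n, f) sample.int(K, n, replace = TRUE, prob = f)
    hap_of <- c(draw(cfg$n_historic, f_hist), draw(cfg$n_contemporary, f_cont))
    epoch <- c(rep("historic", cfg$n_historic),
               rep("contemporary", cfg$n_contemporary))
    ids <- sprintf("MT_%s%03d", ifelse(epoch == "historic", "HIS", "CON"),
                   c(seq_len(cfg$n_historic), seq_len(cfg$n_contemporary)))
    seqs <- key[hap_of]
    names(seqs) <- sprintf("%s|epoch=%s|pop=SIM", ids, epoch)
    list(
      sequences = seqs,
      assignments = data.frame(id = ids, epoch = epoch, pop = "SIM",
                               haplotype = sprintf("hap%02d", hap_of),
                               stringsAsFactors = FALSE),
      truth = list(
        haplotypes = stats::setNames(key, sprintf("hap%02d", seq_len(K))),
        freq_historic = f_hist,
        freq_contemporary = f_cont
      )
    )
  })
}
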