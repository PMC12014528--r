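#' Write genotype likelihoods in BEAGLE-GL text format
#'
#' One row per marker: marker name (`scaffold_pos`), major and minor allele
#' codes (A=0, C=1, G=2, T=3), then one linear-scale triplet per individual
#' (normalized so the maximum is 1), at 6 significant digits.
#'
#' @param gl An `erosion_gl`.
#' @param path Output file.
#' @export
write_beagle_gl <- function(gl, path) {
  stopifnot(inherits(gl, "erosion_gl"))
  ids <- dimnames(gl$loglik)[[2]]
  N <- length(ids)
  lin <- exp(gl$loglik)
  trip <- matrix("", length(gl$pos), 3 * N)
  for (i in seq_len(N)) {
    trip[, 3 * i - 2] <- signif(lin[, i, 1], 6)
    trip[, 3 * i - 1] <- signif(lin[, i, 2], 6)
    trip[, 3 * i] <- signif(lin[, i, 3], 6)
  }
  hdr <- c("marker", "allele1", "allele2",
           as.vector(t(matrix(rep(ids, 3), ncol = 3))))
  body <- cbind(paste(gl$scaffold, gl$pos, sep = "_"),
                match(gl$major, BASES) - 1L,
                match(gl$minor, BASES) - 1L,
                trip)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BEAGLE-GL text file
#' @param path Input file written by [write_beagle_gl()] (or ANGSD-style).
#' @return An `erosion_gl` (maf unset; `has_data` TRUE where the triplet is
#'   not flat).
#' @export
read_beagle_gl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty BEAGLE file")
  hdr <- strsplit(lines[1], "\t")[[1]]
  N <- (length(hdr) - 3) / 3
  if (N != round(N) || N < 1) stop("malformed BEAGLE header: column count")
  ids <- hdr[seq(4, length(hdr), by = 3)]
  S <- length(lines) - 1
  loglik <- array(0, c(S, N, 3), dimnames = list(NULL, ids, c("MM", "Mm", "mm")))
  marker <- character(S); a1 <- integer(S); a2 <- integer(S)
  for (s in seq_len(S)) {
    f <- strsplit(lines[s + 1], "\t")[[1]]
    if (length(f) != length(hdr)) {
      stop("malformed BEAGLE row ", s + 1, ": expected ", length(hdr),
           " columns, found ", length(f))
    }
    marker[s] <- f[1]
    a1[s] <- as.integer(f[2]); a2[s] <- as.integer(f[3])
    v <- as.numeric(f[-(1:3)])
    loglik[s, , ] <- matrix(v, N, 3, byrow = TRUE)
  }
  loglik <- log(pmax(loglik, 1e-300))
  mx <- pmax(loglik[, , 1], loglik[, , 2], loglik[, , 3])
  for (g in 1:3) loglik[, , g] <- loglik[, , g] - mx
  sp <- regmatches(marker, regexpr("_[0-9]+$", marker))
  pos <- as.integer(sub("_", "", sp))
  scaffold <- sub("_[0-9]+$", "", marker)
  flat <- loglik[, , 1] == 0 & loglik[, , 2] == 0 & loglik[, , 3] == 0
  structure(list(
    scaffold = scaffold, pos = pos,
    major = BASES[a1 + 1L], minor = BASES[a2 + 1L],
    loglik = loglik,
    has_data = !flat,
    maf = rep(NA_real_, S),
    individuals = data.frame(id = ids, epoch = NA_character_,
                             stringsAsFactors = FALSE)
  ), class = "erosion_gl")
}

#' Write hard genotypes as a minimal VCF v4.2
#'
#' CHROM/POS/REF/ALT/GT only, biallelic sites; missing genotypes as `./.`.
#'
#' @param geno An `erosion_geno`.
#' @param path Output file.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "erosion_geno"))
  ids <- geno$individuals$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=erosionkit %s", as.character(utils::packageVersion("erosionkit"))),
    sprintf("##contig=<ID=%s,length=%d>", names(geno$scaffold_lengths),
            as.integer(geno$scaffold_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(geno$sites), length(ids))
  for (i in seq_along(ids)) {
    g <- geno$geno[ids[i], ]
    gt[!is.na(g), i] <- gt_code[as.character(g[!is.na(g)])]
  }
  body <- cbind(geno$sites$scaffold, geno$sites$pos, ".",
                geno$sites$ref, geno$sites$alt, ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read hard genotypes from a VCF
#'
#' Keeps biallelic SNPs only; missing genotypes become NA; 1-based positions
#' are preserved; records on excluded scaffolds are dropped. Records whose
#' column count disagrees with the header are rejected with their line
#' number before parsing.
#'
#' @param path VCF file (v4.x with GT).
#' @param samples Optional sample-id subset.
#' @param exclude_scaffolds Scaffold names to drop (e.g. sex scaffolds).
#' @return List: `geno` (individuals x sites dose matrix), `sites`
#'   (scaffold, pos, ref, alt), `samples`.
#' @export
read_vcf_genotypes <- function(path, samples = NULL,
                               exclude_scaffolds = character()) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("malformed VCF: missing #CHROM header")
  ncol_exp <- length(strsplit(lines[hdr_i], "\t")[[1]])
  for (j in seq(hdr_i + 1, length.out = length(lines) - hdr_i)) {
    nf <- length(strsplit(lines[j], "\t")[[1]])
    if (nf != ncol_exp) {
      stop("malformed VCF record at line ", j, ": ", nf, " fields, expected ",
           ncol_exp)
    }
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !grepl(",", fix[, "ALT"]) &
          nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
          !(fix[, "CHROM"] %in% exclude_scaffolds)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  dose <- matrix(NA_integer_, ncol(gt), nrow(gt),
                 dimnames = list(colnames(gt), NULL))
  clean <- gsub("\\|", "/", gt)
  dose_map <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  for (i in seq_len(ncol(gt))) {
    dose[i, ] <- unname(dose_map[clean[, i]])
  }
  list(
    geno = dose,
    sites = data.frame(scaffold = unname(fix[, "CHROM"]),
                       pos = as.integer(fix[, "POS"]),
                       ref = unname(fix[, "REF"]), alt = unname(fix[, "ALT"]),
                       stringsAsFactors = FALSE),
    samples = rownames(dose)
  )
}

#' Write genotypes as PLINK PED/MAP text files
#' @param geno An `erosion_geno`.
#' @param prefix Output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @export
write_ped_map <- function(geno, prefix) {
  stopifnot(inherits(geno, "erosion_geno"))
  map <- data.frame(chr = geno$sites$scaffold,
                    id = paste(geno$sites$scaffold, geno$sites$pos, sep = "_"),
                    cm = 0, pos = geno$sites$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- geno$individuals$id
  S <- nrow(geno$sites)
  ped <- matrix("0", length(ids), 6 + 2 * S)
  ped[, 1] <- ids; ped[, 2] <- ids
  ped[, 5] <- "0"; ped[, 6] <- "-9"
  for (i in seq_along(ids)) {
    g <- geno$geno[ids[i], ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, geno$sites$alt, geno$sites$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, geno$sites$alt, geno$sites$ref))
    ped[i, seq(7, by = 2, length.out = S)] <- a1
    ped[i, seq(8, by = 2, length.out = S)] <- a2
  }
  writeLines(apply(ped, 1, paste, collapse = " "), paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK PED/MAP text files into a dose matrix
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return List: `geno` (individuals x sites minor-allele-agnostic dose,
#'   counted against the first allele seen per site as reference), `sites`.
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chr", "id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped_lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(ped_lines, " ")
  S <- nrow(map)
  n <- length(parts)
  ids <- vapply(parts, `[`, "", 2)
  a1 <- do.call(rbind, lapply(parts, function(p) p[seq(7, by = 2, length.out = S)]))
  a2 <- do.call(rbind, lapply(parts, function(p) p[seq(8, by = 2, length.out = S)]))
  ref <- apply(rbind(a1, a2), 2, function(col) {
    col <- col[col != "0"]
    if (length(col)) col[1] else "0"
  })
  dose <- (a1 != matrix(ref, n, S, byrow = TRUE)) +
          (a2 != matrix(ref, n, S, byrow = TRUE))
  dose[a1 == "0" | a2 == "0"] <- NA
  rownames(dose) <- ids
  list(geno = dose, sites = map)
}

#' Write a pileup as a wide TSV (internal format)
#'
#' Header comment lines carry the constant base quality and the individual
#' ids with their epochs; one row per site with four count columns (A, C, G,
#' T) per individual. Round-trips exactly.
#'
#' @param pileup An `erosion_pileup`.
#' @param path Output file.
#' @export
write_pileup_tsv <- function(pileup, path) {
  stopifnot(inherits(pileup, "erosion_pileup"))
  ids <- pileup$individuals$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#qual=%.6g", pileup$qual), con)
  writeLines(sprintf("#individual=%s,epoch=%s", ids,
                     pileup$individuals$epoch), con)
  hdr <- c("scaffold", "pos",
           paste(rep(ids, each = 4), rep(BASES, length(ids)), sep = "."))
  writeLines(paste(hdr, collapse = "\t"), con)
  flat <- do.call(cbind, lapply(seq_along(ids), function(i) {
    pileup$counts[, i, , drop = TRUE]
  }))
  body <- cbind(pileup$scaffold, pileup$pos, flat)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a pileup written by [write_pileup_tsv()]
#' @param path Input file.
#' @return An `erosion_pileup`.
#' @export
read_pileup_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  qual <- as.numeric(sub("^#qual=", "", grep("^#qual=", meta, value = TRUE)))
  ind <- sub("^#individual=", "", grep("^#individual=", meta, value = TRUE))
  ids <- sub(",epoch=.*$", "", ind)
  epoch <- sub("^.*,epoch=", "", ind)
  body <- lines[!grepl("^#", lines)]
  hdr <- strsplit(body[1], "\t")[[1]]
  if (length(hdr) != 2 + 4 * length(ids)) {
    stop("malformed pileup TSV: header/individual mismatch")
  }
  d <- utils::read.table(text = body[-1], sep = "\t",
                         colClasses = c("character",
                                        rep("integer", length(hdr) - 1)))
  S <- nrow(d)
  counts <- array(0L, c(S, length(ids), 4L),
                  dimnames = list(NULL, ids, BASES))
  for (i in seq_along(ids)) {
    counts[, i, ] <- as.matrix(d[, 2 + (4 * i - 3):(4 * i), drop = FALSE])
  }
  structure(list(
    scaffold = d[[1]],
    pos = d[[2]],
    counts = counts,
    qual = qual,
    individuals = data.frame(id = ids, epoch = epoch, stringsAsFactors = FALSE)
  ), class = "erosion_pileup")
}

#' Write labelled sequences as FASTA
#' @param sequences Named character vector (names become headers).
#' @param path Output file.
#' @export
write_labelled_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a FASTA alignment, keeping header labels
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_labelled_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write scaffold lengths as a FAI-style TSV (name, length)
#' @param scaffold_lengths Named numeric vector.
#' @param path Output file.
#' @export
write_fai <- function(scaffold_lengths, path) {
  utils::write.table(
    data.frame(name = names(scaffold_lengths),
               length = as.integer(scaffold_lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read scaffold lengths from a FAI-style TSV
#' @param path File whose first two columns are name and length.
#' @return Named numeric vector.
#' @export
read_fai <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2]]), d[[1]])
}

#' Write the simulation truth table as TSV
#' @param geno An `erosion_geno` (after any [plant_roh()] calls).
#' @param path Output file.
#' @export
write_truth_table <- function(geno, path) {
  stopifnot(inherits(geno, "erosion_geno"))
  df <- data.frame(id = geno$individuals$id,
                   epoch = geno$individuals$epoch,
                   true_het = unname(geno$truth$het[geno$individuals$id]),
                   true_froh = unname(geno$truth$froh[geno$individuals$id]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
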