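#!/usr/bin/env Rscript
# Stage 6: genotype-likelihood population structure on the filtered
# transversion SNPs - covariance PCA and admixture EM for K = 2 and 3,
# keeping the best of the random starts per K.

library(erosionkit)

gl <- read_beagle_gl("results/filtered.beagle.tsv")
gl <- estimate_maf_em(gl)
truth <- read.delim("results/data/truth.tsv")
epoch <- truth$epoch[match(gl$individuals$id, truth$id)]

cv <- gl_covariance(gl)
pc <- pca_covariance(cv)
scores <- data.frame(id = rownames(pc$scores), epoch = epoch,
                     pc$scores[, 1:4])
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s1 <- pc$scores[, 1]
side <- sign(median(s1[epoch == "historic"]))
mis <- sum(sign(s1[epoch == "historic"]) != side) +
  sum(sign(s1[epoch == "contemporary"]) != -side)
cat(sprintf("PCA on %d sites: PC1 explains %.1f%%; %d of %d individuals off their epoch side\n",
            cv$n_sites, 100 * pc$values[1] / sum(pmax(pc$values, 0)), mis,
            length(s1)))

for (K in 2:3) {
  fit <- admixture_em(gl, K = K, seed = 600L + K, n_starts = 20)
  q <- data.frame(id = rownames(fit$Q), epoch = epoch, round(fit$Q, 4))
  write.table(q, sprintf("results/admixture_Q_K%d.tsv", K), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("K = %d: best log-likelihood %.2f over %d starts, mean max-q %.3f\n",
              K, fit$loglik, length(fit$start_logliks),
              mean(apply(fit$Q, 1, max))))
}
cat("wrote results/pca_scores.tsv, results/admixture_Q_K*.tsv\n")
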