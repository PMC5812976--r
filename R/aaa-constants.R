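# Shared label sets and index bookkeeping (defined first in the collate
# order; the six phenogenotype states are ordered AA1, Aa1, aa1, AA2, Aa2,
# aa2 throughout).

GENOTYPES <- c("AA", "Aa", "aa")
PAIR_LABELS <- c("1x1", "1x2", "2x1", "2x2")

# map an ordered parental phenotype pair to its table row
pair_row <- function(phi_m, phi_f) {
  if (!all(phi_m %in% 1:2) || !all(phi_f %in% 1:2))
    stop("parental phenotypes must be 1 or 2", call. = FALSE)
  2L * (phi_m - 1L) + phi_f
}

genotype_index <- function(genotype) {
  idx <- match(genotype, GENOTYPES)
  if (anyNA(idx))
    stop(sprintf("unknown genotype label: '%s' (use AA, Aa or aa)",
                 paste(genotype[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  idx
}

# Mendelian segregation array men[g_m, g_f, g_offspring]
mendel_array <- local({
  gam <- rbind(AA = c(1, 0), Aa = c(0.5, 0.5), aa = c(0, 1))  # P(A), P(a)
  men <- array(0, dim = c(3, 3, 3),
               dimnames = list(GENOTYPES, GENOTYPES, GENOTYPES))
  for (i in 1:3) for (j in 1:3) {
    pA_m <- gam[i, 1]; pA_f <- gam[j, 1]
    men[i, j, 1] <- pA_m * pA_f
    men[i, j, 2] <- pA_m * (1 - pA_f) + (1 - pA_m) * pA_f
    men[i, j, 3] <- (1 - pA_m) * (1 - pA_f)
  }
  men
})

# phenogenotype index bookkeeping for the length-6 state vector
PG_GENO <- rep(1:3, 2L)        # genotype of state i
PG_PHEN <- rep(1:2, each = 3L) # phenotype of state i
PG_PAIR <- matrix(pair_row(rep(PG_PHEN, 6L), rep(PG_PHEN, each = 6L)), 6L, 6L)
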