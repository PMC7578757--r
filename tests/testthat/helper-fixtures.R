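# Published count-table fixtures, rebuilt in code.

# progeny segregation table: observed (WZ/ZZ pooled, WW) counts and
# the printed p-values
table1Counts <- list(c(66, 17), c(56, 12), c(42, 19))
table1P <- c(0.34, 0.16, 0.27)

# native-population genotyped females: (WZ, WW) counts and printed WW%
table3Females <- list(A = c(305, 2), B = c(284, 3),
                      C = c(284, 2), D = c(294, 0))
table3WWpct <- c(A = 0.65, B = 1.05, C = 0.70, D = 0.00)

# build a minimal cohort data.frame from per-class counts
makeCohort <- function(nMale = 0, nIntersex = 0, nWZ = 0, nWW = 0,
                       nFemaleNA = 0, site = "s1") {
  data.frame(
    id = paste0("i", seq_len(nMale + nIntersex + nWZ + nWW + nFemaleNA)),
    site = site,
    phenotype = c(rep("male", nMale), rep("intersex", nIntersex),
                  rep("female", nWZ + nWW + nFemaleNA)),
    genotype = c(rep("ZZ", nMale), rep("WZ", nIntersex),
                 rep("WZ", nWZ), rep("WW", nWW),
                 rep(NA_character_, nFemaleNA)),
    stringsAsFactors = FALSE)
}

ltsdExpected <- c(ZZ = 47.96, IS = 2.04, WZ = 48.96, WW = 1.04)
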