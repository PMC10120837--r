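# Small fixtures built in code.

# 4-individual x 3-marker genotype CSV with the two-row header dialect.
write_tiny_geno_csv <- function(path) {
  writeLines(c(
    "id,m1,m2,m3",
    "segtype,testcross2,intercross3,testcross2",
    "ind1,aa,AA,ab",
    "ind2,ab,Aa,aa",
    "ind3,aa,aa,",
    "ind4,ab,Aa,ab"
  ), path)
  path
}

make_pheno <- function(values) {
  PhenotypeTable(values)
}

# A small simulated dataset shared by scan tests.
tiny_cross <- function(seed = 11, n = 120, lgs = 2, mpg = 12, spacing = 5) {
  simulateCross(crossSpec(nProgeny = n, linkageGroups = lgs,
                          markersPerGroup = mpg, markerSpacing = spacing,
                          seed = seed))
}
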