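# shared structure strings
MAN3_STR <- "GlcNAc(GlcNAc(Man(Man[6])(Man[3])))"
BIANT_STR <- "GlcNAc(GlcNAc(Man(Man[6](GlcNAc(Gal)))(Man[3](GlcNAc(Gal)))))"
BIANT_BIS_STR <-
  "GlcNAc(GlcNAc(Man(GlcNAc[bis])(Man[6](GlcNAc(Gal)))(Man[3](GlcNAc(Gal)))))"
HYBRID_STR <- "GlcNAc(GlcNAc(Man(Man[6](Man)(Man))(Man[3](GlcNAc(Gal)))))"
SIAL_BI_STR <- paste0("GlcNAc(Fuc[cf])(GlcNAc(Man(Man[6](GlcNAc(Gal(NeuAc))))",
                      "(Man[3](GlcNAc(Gal)))))")

# independent brute-force step-up FDR oracle
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_along(p), function(i) {
    eligible <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[eligible] / rank(p, ties.method = "max")[eligible]))
  }, numeric(1))
}

# independent all-pairs Manhattan-distance adjacency oracle
edges_oracle <- function(comps) {
  M <- t(vapply(comps, function(s) unclass(parse_composition(s)), integer(4)))
  out <- character(0)
  n <- nrow(M)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sum(abs(M[i, ] - M[j, ])) == 1) {
      pair <- sort(c(comps[i], comps[j]))
      out <- c(out, paste(pair[1], pair[2]))
    }
  }
  sort(out)
}

# random composition strings for property tests
random_comps <- function(n, seed) {
  set.seed(seed)
  unique(vapply(seq_len(n), function(i) {
    format_composition(glycan_composition(
      hex = sample(0:10, 1), hexnac = sample(0:8, 1),
      fuc = sample(0:3, 1), neuac = sample(0:4, 1)))
  }, character(1)))
}
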