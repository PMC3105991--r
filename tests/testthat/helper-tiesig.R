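## Shared helpers for the test suite: tiny deterministic dataset builders
## and canonical-form utilities for comparing signature collections.

sigKeys <- function(x) {
  sigs <- if (methods::is(x, "SignatureSet")) signatures(x) else x
  sort(vapply(sigs, function(s) paste(sort(s), collapse = ","), character(1)))
}

## Dataset with one strong gene (phenotype + noise), optional exact copy of
## it, and `nNoise` independent noise genes.
makeSignalData <- function(n = 300, nNoise = 10, withCopy = FALSE, seed = 1) {
  set.seed(seed)
  ph <- rep(c(0L, 1L), length.out = n)
  sig <- as.numeric(ph) + rnorm(n, sd = 0.4)
  X <- cbind(sig = sig)
  if (withCopy)
    X <- cbind(X, sigCopy = 0.3 + 1.5 * sig + rnorm(n, sd = 1e-6))
  X <- cbind(X, matrix(rnorm(n * nNoise), n,
                       dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
  ExpressionDataset(X, phenotype = ph)
}

## Tiny samples x genes matrix with exactly known values for IO round-trips.
makeToyMatrix <- function() {
  matrix(c(1, 2.5, -3, 4,
           0.5, 0, 7.25, -1,
           2, 3, 4.5, 5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("s1", "s2", "s3"),
                         c("gA", "gB", "gC", "gD")))
}
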