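# Named indicator vector with the given indicators set.
flags_with <- function(...) {
  v <- setNames(rep(FALSE, 13), mfi_indicators())
  on <- c(...)
  if (length(on)) v[on] <- TRUE
  v
}

# All 2^13 indicator vectors as a 0/1 matrix with canonical column names.
all_indicator_vectors <- function() {
  m <- as.matrix(expand.grid(rep(list(0:1), 13)))
  colnames(m) <- mfi_indicators()
  m
}

# Tiny record table with explicit destination counts, complete covariates.
records_with_counts <- function(counts, specialty = "general") {
  dest <- rep(names(counts), counts)
  n <- length(dest)
  rec <- data.frame(record_id = sprintf("T%04d", seq_len(n)),
                    specialty = specialty, stringsAsFactors = FALSE)
  for (k in mfi_indicators()) rec[[k]] <- 0L
  rec$age <- 60L + seq_len(n) %% 20
  rec$sex <- rep(c("male", "female"), length.out = n)
  rec$wrvu <- 20 + seq_len(n) %% 7
  rec$asa_class <- 1L + seq_len(n) %% 4
  rec$destination <- dest
  rec
}

# Two well-separated Gaussian blobs; linearly separable 2-class toy.
separable_toy <- function(n = 200, seed = 42) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(cbind(rnorm(half, 0.2, 0.05), rnorm(half, 0.2, 0.05)),
             cbind(rnorm(half, 0.8, 0.05), rnorm(half, 0.8, 0.05)))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = factor(rep(c("neg", "pos"), each = half)))
}
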