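# Small fixture builders shared across test files.

toy_atlas_csv <- function(path, n = 4, subnetworks = c("default mode",
                                                       "occipital")) {
  df <- data.frame(label = paste0("roi", seq_len(n)),
                   x = seq_len(n), y = -seq_len(n), z = seq_len(n),
                   subnetwork = rep_len(subnetworks, n))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

toy_atlas <- function(n = 4, subnetworks = c("default mode", "occipital")) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  load_atlas(toy_atlas_csv(f, n, subnetworks))
}

toy_cohort <- function(n_per_group = 6, sites = "S1", seed = 1,
                       fd = NULL, tr = 2) {
  set.seed(seed)
  n <- 2 * n_per_group * length(sites)
  df <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("ASD", "TD"), length.out = n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = runif(n, 8, 30),
    mean_fd = if (is.null(fd)) runif(n, 0.02, 0.15) else rep_len(fd, n),
    site = rep(sites, each = 2 * n_per_group),
    ados_total = ifelse(rep(c(TRUE, FALSE), length.out = n),
                        rpois(n, 8), rbinom(n, 1, 0.1)),
    tr_seconds = rep_len(tr, n),
    stringsAsFactors = FALSE)
  as_cohort(df)
}

# atlas subsample keeping subnetwork proportions (used for scaled-down
# cohort simulations)
subsample_atlas <- function(n_total, seed = 1) {
  atlas <- dosenbach_atlas()
  set.seed(seed)
  idx <- unlist(lapply(levels(atlas$subnetwork), function(sn) {
    members <- which(atlas$subnetwork == sn)
    take <- max(2, round(n_total * length(members) / 160))
    sort(sample(members, take))
  }))
  new_env <- list(labels = atlas$labels[idx],
                  coords = atlas$coords[idx, , drop = FALSE],
                  subnetwork = factor(as.character(atlas$subnetwork[idx]),
                                      levels = levels(atlas$subnetwork)))
  structure(new_env, class = "flex_atlas")
}

# planted two-block static multilayer network: 2 blocks, within/between
# weights, T identical layers
planted_block_net <- function(n = 8, T = 3, within = 0.9, between = 0,
                              jitter = 0, seed = 1) {
  set.seed(seed)
  block <- rep(1:2, each = n / 2)
  W <- matrix(between, n, n)
  W[outer(block, block, "==")] <- within
  tensor <- array(0, dim = c(n, n, T))
  for (s in seq_len(T)) {
    L <- W
    if (jitter > 0) {
      J <- matrix(runif(n * n, -jitter, jitter), n, n)
      L <- pmax(L + (J + t(J)) / 2, 0)
    }
    diag(L) <- 0
    tensor[, , s] <- L
  }
  dynamic_network(tensor)
}
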