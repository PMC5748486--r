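# Shared test fixtures and independent oracles.

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("regionith-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

# Build a presence_matrix directly from a state matrix (rows = mutations,
# columns = samples; entries "present"/"absent"/"missing").
mk_presence <- function(state, samples = NULL, mutations = NULL) {
  if (is.null(samples))
    samples <- data.frame(sample = colnames(state), role = "biopsy",
                          area = paste0("A", seq_len(ncol(state))),
                          stringsAsFactors = FALSE)
  if (is.null(mutations))
    mutations <- data.frame(id = rownames(state), stringsAsFactors = FALSE)
  pm <- structure(list(state = state, af = NULL, mutations = mutations,
                       samples = samples, sharing = NULL,
                       carrier_n = rowSums(state == "present"),
                       filter_log = list(admitted = nrow(state),
                                         germline_excluded = character(0),
                                         uncalled = character(0),
                                         mask_dropped = character(0))),
                  class = "presence_matrix")
  classify_sharing(pm)
}

# Presence matrix from a list of carrier label vectors.
mk_presence_sets <- function(carrier_sets, samples) {
  state <- t(vapply(carrier_sets, function(cs)
    ifelse(samples %in% cs, "present", "absent"), character(length(samples))))
  dimnames(state) <- list(names(carrier_sets), samples)
  mk_presence(state)
}

# Random presence matrix used for search benchmarks.
random_state <- function(n_samples, n_mut, p_present = 0.5, p_missing = 0) {
  st <- matrix(ifelse(runif(n_samples * n_mut) < p_present,
                      "present", "absent"),
               n_mut, n_samples,
               dimnames = list(sprintf("m%03d", seq_len(n_mut)),
                               paste0("s", seq_len(n_samples))))
  if (p_missing > 0) st[runif(length(st)) < p_missing] <- "missing"
  st <- st[rowSums(st == "present") > 0, , drop = FALSE]
  st[, colSums(st != "missing") > 0, drop = FALSE]
}

# --- independent rank-test oracles (full enumeration / permutation) -------

# Exact two-sided rank-sum p by enumerating all group assignments.
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  w_all <- apply(combos, 2, function(idx)
    sum(r[idx]) - length(a) * (length(a) + 1) / 2)
  mu <- length(a) * length(b) / 2
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}

# Exact two-sided signed-rank p by enumerating all sign patterns.
enum_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9))
}

# Monte-Carlo permutation two-sided p for the rank-sum setting.
perm_rank_sum_p <- function(a, b, B = 10000) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  mu <- na * length(b) / 2
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  hits <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(length(pooled), na)
    w <- sum(r[idx]) - na * (na + 1) / 2
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# Monte-Carlo sign-flip two-sided p for the signed-rank setting.
perm_signed_rank_p <- function(a, b, B = 10000) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  mu <- length(d) * (length(d) + 1) / 4
  v_obs <- sum(r[d > 0])
  hits <- 0L
  for (i in seq_len(B)) {
    v <- sum(r[runif(length(d)) < 0.5])
    if (abs(v - mu) >= abs(v_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# Locate the packaged toy fixture whether running from source or installed.
toy_fixture <- function(name) {
  p <- system.file("extdata", name, package = "regionith")
  if (nzchar(p)) p else testthat::test_path("..", "..", "inst", "extdata", name)
}
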