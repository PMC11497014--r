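# shared fixtures, built in code at test time

# a small, fast simulation configuration (analysis behaviour, not study scale)
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_donor_clones = 300L, n_donor_cells = 400L,
         n_recipient_cells = 400L, n_denovo_clones = 500L,
         n_genes = 300L, markers_per_type = 10L),
    list(...))
  do.call(sim_config, args)
}

# cell table for a pair with explicit clonotype keys
toy_cells <- function(keys, role, pair_id = "P1", group = "MSDT",
                      subset = "Teff", prefix = role) {
  data.frame(barcode = sprintf("%s-%03d", prefix, seq_along(keys)),
             subject_id = paste0(pair_id, "-", substr(role, 1, 1)),
             pair_id = pair_id, role = role, group = group,
             subset = rep_len(subset, length(keys)),
             clonotype_key = keys, stringsAsFactors = FALSE)
}

# write a minimal 10x-style contig CSV and return its path
write_tenx_fixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(rows, path, sep = ",")
  path
}

# independent exact two-sided rank-sum oracle: enumerate every assignment of
# the pooled values to the first group and count pairwise wins (Mann-Whitney
# U with 0.5 per tie), then apply the doubled-tail convention
ranksum_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  us <- utils::combn(length(pooled), m, FUN = function(idx)
    u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(k) m * p[ord[k]] / k, numeric(1))
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}
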