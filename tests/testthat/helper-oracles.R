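# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths: plain loops, utils::combn enumeration and naive
# set membership only.

# exact two-sided permutation p on |mean difference|, enumerating every
# assignment of the pooled values to the first group
oracle_perm_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(length(pool), nx)
  stat <- numeric(ncol(idx))
  for (j in seq_len(ncol(idx))) {
    a <- pool[idx[, j]]
    b <- pool[-idx[, j]]
    stat[j] <- abs(mean(a) - mean(b))
  }
  mean(stat >= obs - 1e-12)
}

# per-element membership enumeration of all 7 exclusive venn regions
oracle_venn <- function(A, B, C) {
  u <- unique(c(A, B, C))
  counts <- c(a_only = 0, b_only = 0, c_only = 0, ab_only = 0, ac_only = 0,
              bc_only = 0, abc = 0)
  for (g in u) {
    ina <- g %in% A; inb <- g %in% B; inc <- g %in% C
    key <- if (ina && inb && inc) "abc"
      else if (ina && inb) "ab_only"
      else if (ina && inc) "ac_only"
      else if (inb && inc) "bc_only"
      else if (ina) "a_only" else if (inb) "b_only" else "c_only"
    counts[key] <- counts[key] + 1
  }
  counts
}

# a minimal single-plate well table; ratios are set exactly by using a
# constant renilla of 1000 and firefly = ratio * 1000
make_plate <- function(pool_ratios, control_ratios, plate_id = "P001",
                       pool_id = "POOLX") {
  stopifnot(length(control_ratios) >= 2)
  tibble::tibble(
    plate_id = plate_id,
    well_id = wntscreen:::well_labels(length(pool_ratios) + length(control_ratios)),
    sample_kind = c(rep("pool", length(pool_ratios)),
                    rep("negative_control", length(control_ratios))),
    pool_id = c(rep(pool_id, length(pool_ratios)),
                rep(NA_character_, length(control_ratios))),
    firefly = c(pool_ratios, control_ratios) * 1000,
    renilla = 1000,
    replicate = 1L
  )
}

write_well_tsv <- function(wells, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(wells, path, na = "NA")
  path
}
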