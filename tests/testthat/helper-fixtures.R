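# In-code fixtures and independent oracles shared across the suite.

make_subjects <- function(status, fh = "unknown", province = NA_character_,
                          age = 40, prefix = "S") {
  n <- length(status)
  data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    status = status,
    age = rep_len(age, n),
    family_history = rep_len(fh, n),
    province = rep_len(province, n),
    stringsAsFactors = FALSE
  )
}

make_variants <- function(subject_id, hgvs_c, gene = "BRCA1",
                          classification = "pathogenic") {
  df <- data.frame(
    subject_id = subject_id,
    gene = rep_len(gene, length(subject_id)),
    hgvs_c = hgvs_c,
    classification = rep_len(classification, length(subject_id)),
    stringsAsFactors = FALSE
  )
  coords <- parse_cdna(df$hgvs_c)
  df$cds_base <- coords$base
  df$cds_offset <- coords$offset
  df
}

# Expand a status-level count table (status, n, carriers) into full subject
# and variant tables: each carrier gets one pathogenic BRCA1 variant.
cohort_from_counts <- function(counts) {
  subjects <- make_subjects(rep(counts$status, counts$n))
  carrier_ids <- unlist(mapply(
    function(st, n, k) {
      ids <- subjects$subject_id[subjects$status == st]
      ids[seq_len(k)]
    },
    counts$status, counts$n, counts$carriers,
    SIMPLIFY = FALSE
  ))
  variants <- make_variants(carrier_ids, sprintf("c.%ddelA", 100 + seq_along(carrier_ids)))
  list(subjects = subjects, variants = variants)
}

# Variant table for one gene with a fixed total number of carriers, of which
# named recurrent mutations take the first slots.
recurrent_variant_table <- function(gene, total_carriers, recurrent_counts) {
  ids <- sprintf("%s_%04d", gene, seq_len(total_carriers))
  hgvs <- sprintf("c.%ddelA", 1000 + seq_len(total_carriers))
  at <- 1L
  for (mut in names(recurrent_counts)) {
    k <- recurrent_counts[[mut]]
    hgvs[at:(at + k - 1L)] <- mut
    at <- at + k
  }
  make_variants(ids, hgvs, gene = gene)
}

# Independent step-up FDR oracle, written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# All permutations of a vector (n <= 6 in the suite).
all_perms <- function(v) {
  if (length(v) == 1L) {
    return(matrix(v, 1L))
  }
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Exhaustive minimum max-min bin-count spread over all ways to cut m ordered
# positions (with multiplicities `counts`) into k contiguous bins.
bin_spread_oracle <- function(counts, k) {
  m <- length(counts)
  cum <- cumsum(counts)
  if (k == 1L) {
    return(0L)
  }
  cuts <- utils::combn(m - 1L, k - 1L)
  spreads <- apply(cuts, 2, function(cc) {
    b <- diff(c(0L, cum[cc], cum[m]))
    max(b) - min(b)
  })
  min(spreads)
}

spread_of_bins <- function(bins) max(bins$n_carriers) - min(bins$n_carriers)

# Selection sort driven only by the pairwise comparator, as an ordering
# oracle for coordinate sorting.
comparator_sort <- function(coords) {
  n <- nrow(coords)
  idx <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (compare_cds(coords[idx[j], ], coords[idx[i], ]) < 0) {
        tmp <- idx[i]
        idx[i] <- idx[j]
        idx[j] <- tmp
      }
    }
  }
  coords[idx, , drop = FALSE]
}

write_cohort_fixture <- function(dir) {
  subjects <- make_subjects(c("breast", "ovary", "cancer_free"),
    fh = c("positive", "negative", "negative"),
    province = c("Guangdong", "Sichuan", "Guangdong")
  )
  variants <- make_variants(
    subjects$subject_id[1:2],
    c("c.5470_5477delATTGGGCA", "c.3109C>T"),
    gene = c("BRCA1", "BRCA2")
  )
  write_cohort(list(subjects = subjects, variants = variants), dir)
}
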