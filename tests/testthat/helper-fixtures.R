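# Shared fixture builders. Everything is generated in code; no files.

# A numeric vector of length n with exact sample mean m and sample SD s.
exact_moments <- function(n, m, s) {
  z <- seq_len(n)
  m + s * (z - mean(z)) / sd(z)
}

# Labels tibble for n_high/n_ave/n_low donors with predictable ids.
make_labels <- function(n_high, n_ave, n_low) {
  tibble::tibble(
    donor_id = c(sprintf("H%03d", seq_len(n_high)),
                 sprintf("A%03d", seq_len(n_ave)),
                 sprintf("L%03d", seq_len(n_low))),
    label = rep(c("High", "Ave", "Low"), c(n_high, n_ave, n_low))
  )
}

# PEEP status table for one gene with exact Up/Down counts per group.
# counts: named list group -> c(n, n_up, n_down).
make_peep_gene <- function(gene, counts) {
  purrr::map_dfr(names(counts), function(grp) {
    cn <- counts[[grp]]
    n <- cn[1]; n_up <- cn[2]; n_down <- cn[3]
    tibble::tibble(
      donor_id = sprintf("%s%03d", substr(grp, 1, 1), seq_len(n)),
      gene = gene,
      status = rep(c("Up", "Down", "Norm"),
                   c(n_up, n_down, n - n_up - n_down))
    )
  })
}

labels_for_peep <- function(counts) {
  purrr::map_dfr(names(counts), function(grp) {
    tibble::tibble(
      donor_id = sprintf("%s%03d", substr(grp, 1, 1), seq_len(counts[[grp]][1])),
      label = grp
    )
  })
}

# The published 4-gene pattern table: all 15 compositions with categories.
reference_patterns_4 <- tibble::tibble(
  n_up = c(4, 3, 2, 1, 0, 3, 2, 1, 0, 2, 1, 0, 1, 0, 0),
  n_norm = c(0, 1, 2, 3, 4, 0, 1, 2, 3, 0, 1, 2, 0, 1, 0),
  n_down = c(0, 0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 3, 3, 4),
  code = c("4U0N0D", "3U1N0D", "2U2N0D", "1U3N0D", "0U4N0D", "3U0N1D",
           "2U1N1D", "1U2N1D", "0U3N1D", "2U0N2D", "1U1N2D", "0U2N2D",
           "1U0N3D", "0U1N3D", "0U0N4D"),
  category = c("4-Up", "3-Up", "2-Up", "1-Up", "Others", "Others", "Others",
               "1-Up-1-Down", "Others", "Others", "Others", "Others",
               "Others", "Others", "Others")
)

# Brute-force pattern oracle: all 3^n ordered status tuples collapsed to
# distinct (up, norm, down) count triples.
brute_force_patterns <- function(n_genes) {
  if (n_genes == 0) {
    return(tibble::tibble(n_up = 0L, n_norm = 0L, n_down = 0L))
  }
  grid <- expand.grid(rep(list(c("Up", "Norm", "Down")), n_genes),
                      stringsAsFactors = FALSE)
  tup <- tibble::tibble(
    n_up = as.integer(rowSums(grid == "Up")),
    n_norm = as.integer(rowSums(grid == "Norm")),
    n_down = as.integer(rowSums(grid == "Down"))
  )
  dplyr::distinct(tup)
}
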