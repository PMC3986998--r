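# Independent brute-force oracles for the agreement statistics, kept
# deliberately naive: explicit loops and hand-rolled ranks/sums so they
# share no code path with the package implementations.

# average ranks by explicit tie-block positions
rank_brute <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (1 + ties) / 2
  }
  r
}

# Pearson on hand-computed ranks, via explicit sums
spearman_brute <- function(x, y) {
  rx <- rank_brute(x); ry <- rank_brute(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# pair-counting by explicit double indexing
cross_brute <- function(a, b) {
  tab <- matrix(0L, 3, 3)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1L
  n <- length(a)
  exact <- 0L; opposite <- 0L
  for (i in seq_along(a)) {
    if (a[i] == b[i]) exact <- exact + 1L
    if ((a[i] == 1 && b[i] == 3) || (a[i] == 3 && b[i] == 1)) opposite <- opposite + 1L
  }
  list(table = tab, exact_pct = 100 * exact / n, opposite_pct = 100 * opposite / n)
}

# spreadsheet-style expansion of the weighted-kappa sums
kappa_brute <- function(tab, scheme = "linear") {
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  num <- 0; den <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      w <- if (scheme == "linear") abs(i - j) / 2 else (i - j)^2 / 4
      num <- num + w * tab[i, j]
      den <- den + w * rs[i] * cs[j] / n
    }
  }
  if (num == 0) 1 else unname(1 - num / den)
}

# scale-free weight-recovery check: least-squares scale onto the truth,
# then compare normalized weights within +/- band
ratios_recovered <- function(m, truth, band = 1) {
  s <- sum(m * truth) / sum(truth * truth)
  if (s <= 0) return(FALSE)
  max(abs(m / s - truth)) <= band
}

# naive re-summation of nutrient intake over quantities and densities
nutrients_brute <- function(quantities, composition) {
  nut_cols <- c("fat_g", "saturated_fat_g", "protein_g", "carbohydrate_g",
                "sucrose_g", "fibre_g", "alcohol_g", "vitamin_d_ug",
                "vitamin_c_mg", "calcium_mg", "iron_mg")
  ids <- unique(quantities$participant_id)
  out <- matrix(0, length(ids), length(nut_cols),
                dimnames = list(ids, nut_cols))
  for (k in seq_len(nrow(quantities))) {
    row <- quantities[k, ]
    dens <- composition[composition$item_id == row$item, ]
    for (nc in nut_cols) {
      out[row$participant_id, nc] <- out[row$participant_id, nc] +
        row$g_per_day * dens[[nc]] / 100
    }
  }
  out
}
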