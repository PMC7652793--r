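# Small hand-built fixtures shared across the test files.

make_compounds <- function(ids, classes,
                           match_factor = 900,
                           id_basis = "pure_standard",
                           proxy_standard = "") {
  data.frame(compound_id = ids, name = ids, compound_class = classes,
             match_factor = rep_len(match_factor, length(ids)),
             id_basis = rep_len(id_basis, length(ids)),
             proxy_standard = rep_len(proxy_standard, length(ids)),
             stringsAsFactors = FALSE)
}

# 4 branch cartridges + 2 blanks, 2 compounds, hand-checkable numbers.
# Blank means: cA 1, cB 2. All samples use the 300/200/15 flow settings, so
# ER = 6 * (mass - blank) / leaf_area.
make_tiny_dataset <- function() {
  ids <- c("s1", "s2", "s3", "s4", "bl1", "bl2")
  m <- matrix(c(10, 20,
                12, 18,
                 9, 26,
                11, 22,
                 1,  2,
                 1,  2),
              ncol = 2, byrow = TRUE,
              dimnames = list(ids, c("cA", "cB")))
  samples <- data.frame(
    sample_id = ids,
    experiment = "E1",
    block_id = c("B1", "B1", "B2", "B2", "blank", "blank"),
    branch_id = c("br1", "br2", "br3", "br4", "bl1", "bl2"),
    sample_type = c(rep("branch", 4), rep("blank", 2)),
    larval_density = c(0, 10, 0, 10, NA, NA),
    inflow_rate = 300, cartridge_flow = 200, duration = 15,
    temperature = c(18, 19, 17, 18, 18, 18),
    rh = c(50, 55, 60, 52, 50, 50),
    stringsAsFactors = FALSE)
  leaves <- data.frame(branch_id = paste0("br", 1:4),
                       leaf_area_total = c(200, 180, 220, 190),
                       leaf_area_eaten = c(2, 18, 1, 20),
                       stringsAsFactors = FALSE)
  compounds <- make_compounds(c("cA", "cB"), c("MT", "GLV"))
  bvoc_dataset(peak_table(m), samples, leaves, compounds)
}

# bare numeric matrix of a peak table, for value comparisons
peak_values <- function(pt) {
  m <- unclass(pt)
  attr(m, "blank_subtracted") <- NULL
  m
}

equicorr <- function(p, r) {
  R <- matrix(r, p, p)
  diag(R) <- 1
  R
}

# two well-separated Gaussian clusters for classifier tests
make_separable <- function(n_per = 15, p = 6, shift = 4, seed = 99) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, mean = shift), n_per, p))
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x,
       labels = factor(rep(c("low", "high"), each = n_per),
                       levels = c("low", "high")))
}
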