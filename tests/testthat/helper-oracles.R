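# Independent oracles and small fixture builders used across the suite.

# Brute-force BH step-up: adj_i = min over j with p_j >= p_i of p_j*m/rank_j,
# clipped at 1. O(m^2), deliberately independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  r <- rank(p, ties.method = "max")
  v <- p * m / r
  vapply(seq_len(m), function(i) min(1, min(v[p >= p[i]])), numeric(1))
}

# Brute-force per-object mean intensity: explicit loop over every pixel.
intensity_oracle <- function(signal, labels) {
  sums <- list(); counts <- list()
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      l <- labels[i, j]
      if (l > 0) {
        key <- as.character(l)
        sums[[key]] <- (sums[[key]] %||% 0) + signal[i, j]
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  labs <- sort(as.integer(names(sums)))
  data.frame(label = labs,
             value = vapply(as.character(labs),
                            function(k) sums[[k]] / counts[[k]], numeric(1)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Render Gaussian-profile spots at given centres on a clean background;
# deterministic fixture for segmentation tests.
render_spots <- function(centers, shape = c(96L, 96L), amplitude = 0.7,
                         radius = 5, background = 0.08) {
  img <- matrix(background, shape[1], shape[2])
  sg <- radius / 2
  rs <- seq_len(shape[1]); cs <- seq_len(shape[2])
  for (k in seq_len(nrow(centers))) {
    g <- outer(exp(-(rs - centers[k, 1])^2 / (2 * sg^2)),
               exp(-(cs - centers[k, 2])^2 / (2 * sg^2)))
    img <- img + amplitude * g
  }
  pmin(img, 1)
}

# Minimal hand-built plate table: one plate, given control and compound
# counts.
tiny_plate <- function(ctrl_counts, compound_counts,
                       plate_id = "P001_R1", dose = 1) {
  n_ctrl <- length(ctrl_counts); n_cmp <- length(compound_counts)
  n <- 2 * n_ctrl + n_cmp
  data.frame(
    plate_id = plate_id, layout = 1L, replicate = 1L,
    well = sprintf("%s%02d", LETTERS[(seq_len(n) - 1) %/% 22 + 2],
                   (seq_len(n) - 1) %% 22 + 2),
    row = (seq_len(n) - 1) %/% 22 + 2, col = (seq_len(n) - 1) %% 22 + 2,
    role = c(rep("dox_only_control", n_ctrl), rep("no_dox_control", n_ctrl),
             rep("compound", n_cmp)),
    compound_id = c(rep("", 2 * n_ctrl), sprintf("CMP%04d", seq_len(n_cmp))),
    dose_uM = c(rep(NA_real_, 2 * n_ctrl), rep(dose, n_cmp)),
    nuclei_count = c(ctrl_counts, ctrl_counts * 2, compound_counts),
    stringsAsFactors = FALSE)
}
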