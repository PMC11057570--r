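# Independent geometric oracles, kept deliberately separate from the
# package's product-sum code path.

# Planar shoelace area of the triangle with vertices at radii (x1, x2, x3)
# on axes 120 degrees apart.
shoelace_area <- function(x1, x2, x3) {
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  px <- c(x1, x2, x3) * cos(ang)
  py <- c(x1, x2, x3) * sin(ang)
  i2 <- c(2, 3, 1)
  abs(sum(px * py[i2] - px[i2] * py)) / 2
}

# TAS from its geometric definition: areas of the four triangles computed by
# the shoelace formula, then closeness/severity assembled from the areas.
tas_geometric <- function(x1, x2, x3) {
  c_alpha <- shoelace_area(0.5, 0.5, 0.5)
  c_beta <- shoelace_area(1, 1, 1) - c_alpha
  s_x <- shoelace_area(x1, x2, x3)
  s_xp <- shoelace_area(min(x1, 0.5), min(x2, 0.5), min(x3, 0.5))
  s_beta <- s_x - s_xp
  ind <- as.numeric(x1 >= 0.5 && x2 >= 0.5 && x3 >= 0.5)
  closeness <- (s_xp + s_beta) / (c_alpha + s_beta)
  severity <- ind * s_beta / c_beta
  (closeness + severity) / 2
}

# Pairwise brute-force AUC: probability a positive outranks a negative,
# ties counting one half.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A male Korean subject with every factor exactly at its cutpoint.
at_threshold_record <- function() {
  list(glucose = 100, sbp = 130, dbp = 85, triglycerides = 150,
       hdl = 40, waist = 90, sex = "male", region = "korean")
}
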