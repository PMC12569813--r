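# Independent derivation of the expected index values for the frozen
# 12-tree fixture. Deliberately written from the index definitions with
# no use of the package: adjacency comes from the bisector-interval
# construction, every index is spelled out term by term, and the result
# is written to fixture12_expected.csv next to this script. Run once
# (Rscript derive_fixture12.R) to regenerate both fixture files.

radius <- 10; buffer <- 2
trees <- data.frame(
  id = sprintf("t%02d", 1:12),
  species = c("pinus_yunnanensis", "pinus_yunnanensis", "quercus_acutissima",
              "betula_alnoides", "pinus_yunnanensis", "camellia_sinensis",
              "pinus_yunnanensis", "quercus_acutissima", "pinus_yunnanensis",
              "vaccinium_bracteatum", "pinus_yunnanensis", "betula_alnoides"),
  x = c(0, 3, -2, 1, -4, 4, 6, -6, -1, 2, 8.5, -7),
  y = c(0, 1, 3, -3.5, -2, 4, -1, 2, 6, 7, 3, -5),
  dbh = c(20, 15, 25, 10, 18, 8, 22, 12, 16, 6, 14, 9),
  height = c(12, 10, 14, 8, 11, 5, 13, 9, 10.5, 3, 9.5, 7),
  crown_width = c(4, 3, 5, 2.5, 3.5, 2, 4.5, 2.8, 3.2, 1.5, 3, 2.2),
  crown_length = c(3, 2.5, 4, 2, 3, 1.5, 3.5, 2.2, 2.7, 1.2, 2.4, 1.8),
  age = c(40, 30, 45, 20, 35, 15, 42, 24, 32, 12, 28, 18),
  rel_elev = c(0.5, 0.8, 1.2, 0.3, 0.9, 1.5, 0.2, 1.1, 1.8, 2.0, 0.6, 0.4),
  alive = TRUE, origin = "original", stringsAsFactors = FALSE)

# --- write the fixture stand file ------------------------------------------
dir <- dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE)[1]))
if (is.na(dir) || dir == "") dir <- "."
con <- file.path(dir, "fixture12.csv")
writeLines(c("# radius_m: 10", "# slope_deg: 0", "# aspect: N",
             "# buffer_width_m: 2", "# survey_year: 2022"), con)
suppressWarnings(write.table(trees, con, sep = ",", row.names = FALSE,
                             quote = FALSE, append = TRUE))

# --- adjacency by bisector intervals ---------------------------------------
n <- nrow(trees); x <- trees$x; y <- trees$y
adjacent <- function(i, j) {
  mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
  dx <- x[j] - x[i]; dy <- y[j] - y[i]; len <- sqrt(dx^2 + dy^2)
  ux <- -dy / len; uy <- dx / len
  b <- mx * ux + my * uy; cc <- mx^2 + my^2 - radius^2
  disc <- b^2 - cc
  if (disc <= 0) return(FALSE)
  lo <- -b - sqrt(disc); hi <- -b + sqrt(disc)
  for (k in seq_len(n)[-c(i, j)]) {
    ddx <- x[k] - x[i]; ddy <- y[k] - y[i]
    rhs <- (x[k]^2 + y[k]^2 - x[i]^2 - y[i]^2) / 2 - (mx * ddx + my * ddy)
    slope <- ux * ddx + uy * ddy
    if (abs(slope) < 1e-14) { if (rhs < 0) return(FALSE) }
    else if (slope > 0) hi <- min(hi, rhs / slope)
    else lo <- max(lo, rhs / slope)
    if (hi - lo <= 1e-9) return(FALSE)
  }
  hi - lo > 1e-9
}
adj <- lapply(seq_len(n), function(i)
  Filter(function(j) adjacent(i, j), setdiff(seq_len(n), i)))

core <- which(sqrt(x^2 + y^2) <= radius - buffer + 1e-12)

# --- dominant height and layers --------------------------------------------
area_ha <- pi * radius^2 / 1e4
k_top <- floor(100 * area_ha)                       # = 3
top <- order(trees$height, decreasing = TRUE)[1:k_top]
Hd <- mean(trees$height[top] + trees$rel_elev[top])
FL <- ifelse(trees$height < Hd / 3, -1L,
             ifelse(trees$height > 2 * Hd / 3, 1L, 0L))

# --- lens overlap -----------------------------------------------------------
lens <- function(i, j) {
  r1 <- trees$crown_width[i] / 2; r2 <- trees$crown_width[j] / 2
  d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  if (d >= r1 + r2) return(1.0)                     # no-overlap sentinel
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)) / 2
}

# --- per-reference indexes ---------------------------------------------------
wref <- 0.496
rows <- lapply(core, function(i) {
  nb <- adj[[i]]; m <- length(nb)
  # W over the 4 nearest trees
  d2 <- (x - x[i])^2 + (y - y[i])^2; d2[i] <- Inf
  nb4 <- order(d2)[1:4]
  az <- sort((atan2(x[nb4] - x[i], y[nb4] - y[i]) * 180 / pi) %% 360)
  gaps <- c(diff(az), 360 - (az[4] - az[1]))
  W <- mean(pmin(gaps, 360 - gaps) < 72)
  U <- mean(trees$dbh[nb] > trees$dbh[i])
  M <- mean(trees$species[nb] != trees$species[i])
  nj <- table(trees$species[nb])
  Mc <- min(1, max(0, M / 2 * ((1 - sum(as.numeric(nj)^2) / (m + 1)^2) +
                                 length(nj) / m)))
  z <- length(unique(FL[c(i, nb)]))
  S <- z / 3 * mean(FL[nb] == FL[i])
  L3 <- trees$height * trees$crown_width * trees$crown_length
  Z <- pi * (trees$crown_width[i] / 2)^2
  CI <- sum(sapply(nb, function(j) lens(i, j) * L3[j] / L3[i])) / Z
  data.frame(reference_id = trees$id[i], n = m, W = W, U = U, Mc = Mc,
             S = S, CI = CI)
})
tab <- do.call(rbind, rows)

pop_sd <- function(v) { s <- sqrt(mean((v - mean(v))^2)); if (s == 0) 1 else s }
deltas <- c(w_dev = pop_sd(abs(tab$W - wref)), U = pop_sd(tab$U),
            Mc = pop_sd(tab$Mc), S = pop_sd(tab$S), CI = pop_sd(tab$CI))
contrib <- (1 + tab$Mc / deltas[["Mc"]]) * (1 + tab$S / deltas[["S"]]) /
  ((1 + tab$U / deltas[["U"]]) * (1 + tab$CI / deltas[["CI"]]) *
     (1 + abs(tab$W - wref) / deltas[["w_dev"]]))
L <- mean(contrib)

out <- tab
out$contribution <- contrib
summary_row <- data.frame(reference_id = ".summary", n = nrow(tab),
                          W = mean(tab$W), U = mean(tab$U), Mc = mean(tab$Mc),
                          S = mean(tab$S), CI = mean(tab$CI), contribution = L)
delta_row <- data.frame(reference_id = ".deltas", n = NA,
                        W = deltas[["w_dev"]], U = deltas[["U"]],
                        Mc = deltas[["Mc"]], S = deltas[["S"]],
                        CI = deltas[["CI"]], contribution = NA)
hd_row <- data.frame(reference_id = ".H_d", n = NA, W = Hd, U = NA, Mc = NA,
                     S = NA, CI = NA, contribution = NA)
res <- rbind(out, summary_row, delta_row, hd_row)
write.csv(format(res, digits = 17), file.path(dir, "fixture12_expected.csv"),
          row.names = FALSE, quote = FALSE)
cat("wrote", nrow(res), "rows; L =", format(L, digits = 12), "\n")
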