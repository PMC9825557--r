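# Factorial cell layouts shared by the generator, the fitted models and the
# contrast machinery. Keeping one canonical ordering means generator truth,
# design matrices and posterior draws always refer to the same cells.

# Instruction x Disruption(3) x third factor (Emotion or LatencyBin).
cells_behaviour <- function(f3_levels, f3_name = "f3") {
  g <- expand.grid(instruction = c("Yield", "Oppose"),
                   disruption = c("None", "Ipsi", "Contra"),
                   f3 = f3_levels,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(g)[3] <- f3_name
  g
}

# Instruction x Disruption(3) x Hemifield, for drift rate and start point.
cells_vz <- function(hemifield_levels = c("L", "R")) {
  expand.grid(instruction = c("Yield", "Oppose"),
              disruption = c("None", "Ipsi", "Contra"),
              hemifield = hemifield_levels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Instruction x Disruption presence, for boundary separation and t0.
cells_at <- function() {
  expand.grid(instruction = c("Yield", "Oppose"),
              presence = c("None", "Present"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# Match rows of a trial table to cell indices.
cell_index <- function(table_cols, cells) {
  key_t <- do.call(paste, c(table_cols, sep = "\r"))
  key_c <- do.call(paste, c(cells, sep = "\r"))
  idx <- match(key_t, key_c)
  if (anyNA(idx)) stop("trial with factor combination outside the cell table")
  idx
}

# Equal-weight averaging vector over the selected cells.
wmean <- function(cells, sel) {
  w <- numeric(nrow(cells))
  i <- which(sel)
  if (!length(i)) stop("contrast selects no cells")
  w[i] <- 1 / length(i)
  w
}

# Planned contrast definitions. Each is a weight vector over the canonical
# cells; confound factors (hemifield) never appear: for v/z cells the weights
# average equally over hemifield, implementing "marginalized out".
contrast_defs_behaviour <- function(cells, f3_name, f3_pos_level) {
  I <- cells$instruction; D <- cells$disruption; F3 <- cells[[f3_name]]
  pos <- F3 == f3_pos_level
  patt <- function(instr) {
    (wmean(cells, I == instr & D == "Contra" & pos) -
     wmean(cells, I == instr & D == "Contra" & !pos)) -
    (wmean(cells, I == instr & D == "Ipsi" & pos) -
     wmean(cells, I == instr & D == "Ipsi" & !pos))
  }
  list(
    disruption_presence = wmean(cells, D != "None") - wmean(cells, D == "None"),
    laterality_yield = wmean(cells, I == "Yield" & D == "Contra") -
      wmean(cells, I == "Yield" & D == "Ipsi"),
    laterality_x_f3_yield = patt("Yield"),
    instruction_x_laterality_x_f3 = patt("Oppose") - patt("Yield"),
    f3_main = wmean(cells, pos) - wmean(cells, !pos)
  )
}

contrast_defs_vz <- function(cells) {
  I <- cells$instruction; D <- cells$disruption
  lat <- function(instr) wmean(cells, I == instr & D == "Contra") -
    wmean(cells, I == instr & D == "Ipsi")
  list(laterality_yield = lat("Yield"),
       instruction_x_laterality = lat("Oppose") - lat("Yield"))
}

contrast_defs_at <- function(cells) {
  I <- cells$instruction; P <- cells$presence
  list(
    instruction = wmean(cells, I == "Oppose") - wmean(cells, I == "Yield"),
    disruption_presence = wmean(cells, P == "Present") - wmean(cells, P == "None"),
    instruction_x_disruption =
      (wmean(cells, I == "Oppose" & P == "Present") -
       wmean(cells, I == "Oppose" & P == "None")) -
      (wmean(cells, I == "Yield" & P == "Present") -
       wmean(cells, I == "Yield" & P == "None"))
  )
}
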