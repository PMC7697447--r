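# Builds inst/extdata/tra_default_table.csv, the bundled parameter table.
# Two base-estimate rows are fixed by back-solving published worked examples
# (PROC 10 industrial vapour medium = 50 ppm; PROC 2 professional vapour
# high = 50 ppm); every other base estimate is a representative default the
# user is expected to replace with official ECETOC TRA workbook values.
# Run from the package root: Rscript data-raw/make_default_table.R

suppressPackageStartupMessages(library(dplyr))

anchor <- "worked-example back-solve"
repres <- "representative default; replace with official ECETOC TRA v3 workbook values"
docs   <- "ECETOC TRA v3 documented banding"

# vapour tiers (ppm): low/medium/high per (proc, setting); NA = absent
vap <- tribble(
  ~proc, ~ind, ~prof,
  1,  c(0.01, 0.01, 0.01), c(0.01, 0.01, 0.01),
  2,  c(1, 5, 10),    c(5, 25, 50),
  3,  c(1, 3, 10),    c(3, 15, 30),
  4,  c(2, 10, 20),   c(5, 25, 50),
  5,  c(5, 25, 50),   c(10, 50, 100),
  6,  c(5, 25, 50),   c(10, 50, 100),
  7,  c(5, 25, 50),   NULL,
  8,  c(5, 25, 50),   c(10, 50, 100),
  9,  c(2, 10, 20),   c(5, 25, 50),
  10, c(10, 50, 100), c(10, 50, 100),
  11, NULL,           c(15, 75, 150),
  12, c(5, 25, 50),   c(10, 50, 100),
  13, c(5, 25, 50),   c(10, 50, 100),
  14, c(2, 10, 20),   c(5, 25, 50),
  15, c(1, 5, 10),    c(1, 5, 10),
  16, c(1, 5, 10),    c(2, 10, 20),
  17, c(5, 25, 50),   c(10, 50, 100),
  18, c(2, 10, 20),   c(5, 25, 50),
  19, c(10, 50, 100), c(15, 75, 150),
  20, c(1, 5, 10),    c(2, 10, 20),
  21, c(1, 5, 10),    c(2, 10, 20),
  22, c(5, 25, 50),   c(10, 50, 100),
  23, c(5, 25, 50),   c(10, 50, 100),
  24, c(5, 25, 50),   c(10, 50, 100),
  25, c(5, 25, 50),   c(10, 50, 100),
  26, c(2, 10, 20),   c(5, 25, 50),
  27, c(2, 10, 20),   c(5, 25, 50),
  28, c(5, 25, 50),   c(10, 50, 100)
)

# dust tiers (mg/m3): low/medium/high dustiness
dst <- tribble(
  ~proc, ~ind, ~prof,
  1,  c(0.01, 0.01, 0.01), c(0.01, 0.01, 0.01),
  2,  c(0.01, 0.1, 0.5), c(0.05, 0.5, 1),
  3,  c(0.1, 0.2, 1),   c(0.1, 0.5, 2),
  4,  c(0.1, 1, 2),     c(0.2, 2, 5),
  5,  c(0.2, 2, 5),     c(0.5, 5, 10),
  6,  c(0.2, 2, 5),     c(0.5, 5, 10),
  7,  c(0.5, 5, 10),    NULL,
  8,  c(0.5, 5, 10),    c(1, 10, 20),
  9,  c(0.2, 2, 5),     c(0.5, 5, 10),
  10, c(0.2, 2, 5),     c(0.5, 5, 10),
  11, NULL,             c(1, 10, 20),
  12, c(0.2, 2, 5),     c(0.5, 5, 10),
  13, c(0.2, 2, 5),     c(0.5, 5, 10),
  14, c(0.2, 2, 5),     c(0.5, 5, 10),
  15, c(0.1, 0.5, 1),   c(0.1, 0.5, 1),
  16, c(0.1, 0.5, 1),   c(0.2, 1, 2),
  17, c(0.2, 2, 5),     c(0.5, 5, 10),
  18, c(0.2, 2, 5),     c(0.5, 5, 10),
  19, c(0.5, 5, 10),    c(1, 10, 20),
  20, c(0.1, 0.5, 1),   c(0.2, 1, 2),
  21, c(0.2, 2, 5),     c(0.5, 5, 10),
  22, c(0.5, 5, 10),    c(1, 10, 20),
  23, c(0.5, 5, 10),    c(1, 10, 20),
  24, c(0.5, 5, 10),    c(1, 10, 20),
  25, c(0.5, 5, 10),    c(1, 10, 20),
  26, c(0.5, 5, 10),    c(1, 10, 20),
  27, c(0.2, 2, 5),     c(0.5, 5, 10),
  28, c(0.5, 5, 10),    c(1, 10, 20)
)

expand_phase <- function(tab, phase, units) {
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (setting in c("industrial", "professional")) {
      v <- tab[[if (setting == "industrial") "ind" else "prof"]][[i]]
      if (is.null(v)) next
      rows[[length(rows) + 1]] <- tibble(
        section = "base", proc = tab$proc[i], setting = setting,
        phase = phase, band = c("low", "medium", "high"),
        class = NA_character_, location = NA_character_,
        value = v, units = units, provenance = repres
      )
    }
  }
  bind_rows(rows)
}

base <- bind_rows(expand_phase(vap, "vapour", "ppm"),
                  expand_phase(dst, "dust", "mg/m3"))
base$provenance[base$proc == 10 & base$setting == "industrial" &
                base$phase == "vapour" & base$band == "medium"] <- anchor
base$provenance[base$proc == 2 & base$setting == "professional" &
                base$phase == "vapour" & base$band == "high"] <- anchor

mod <- function(section, class, value, prov = docs, setting = NA, location = NA, proc = NA) {
  tibble(section = section, proc = proc, setting = setting, phase = NA_character_,
         band = NA_character_, class = class, location = location,
         value = value, units = NA_character_, provenance = prov)
}

conc <- mod("concentration", c("<1%", "1-5%", "5-25%", ">25%"), c(0.1, 0.2, 0.6, 1))
dur  <- mod("duration", c("<15 min", "15-60 min", "1-4 h", ">4 h"), c(0.1, 0.2, 0.6, 1))
gv <- bind_rows(
  mod("ventilation", rep(c("basic", "good", "enhanced"), 2), rep(c(1, 0.7, 0.3), 2),
      setting = rep(c("industrial", "professional"), each = 3), location = "indoor"),
  mod("ventilation", "any", c(0.7, 0.7),
      setting = c("industrial", "professional"), location = "outdoor")
)
lev <- bind_rows(lapply(sort(unique(base$proc)), function(p) {
  mod("lev", NA_character_, c(0.1, 0.2),
      setting = c("industrial", "professional"), proc = p,
      prov = "uniform LEV efficacy default (90% industrial / 80% professional)")
}))
lev$provenance[lev$proc == 2 & lev$setting == "professional"] <- anchor
rpe <- mod("rpe", c("none", "90", "95"), c(1, 0.1, 0.05))

out <- bind_rows(base, conc, dur, gv, lev, rpe)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
readr::write_csv(out, "inst/extdata/tra_default_table.csv", na = "")
cat("wrote", nrow(out), "rows\n")
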