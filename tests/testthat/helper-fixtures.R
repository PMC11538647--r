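# Shared fixtures: everything is generated in code at test time.

test_grid <- function(step = 4) spectral_grid(400, 1800, step)

# a minimal two-metabolite library written to a temp CSV and read back,
# exercising the same parser as the packaged fixture
tiny_library <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "name,abbreviation,formula,peaks",
    "alpha,Alp,C2H5NO2,1000:1.0:8;1571:0.5:8",
    "beta,Bet,C3H6O3,700:1.0:8"
  ), path)
  build_reference_library(path, version = "test")
}

# single-peak record for planted-peak tests
one_peak_record <- function(shift = 1571, width = 8) {
  list(name = "probe", abbreviation = "Prb", formula = "C2H5NO2",
       peaks = data.frame(shift = shift, amp = 1, width = width))
}

# SERSome with specified intensity matrix on a grid
manual_sersome <- function(mat, grid, cell_id = "c1", group = "g") {
  sersome(mat, grid, cell_id = cell_id, group = group)
}
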