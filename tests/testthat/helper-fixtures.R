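# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  hit <- .fixture_cache[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixture_cache[[name]] <- val
  val
}

# Small rest/task cohort with default (study-condition) parameters.
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    generate_cohort(n_eh = 2, n_neh = 2, channels_per_hippocampus = 2,
                    duration_s = 40, fs = 2000, seed = 42)
  })
}

tiny_features <- function() {
  fixture("tiny_features", function() extract_features(tiny_cohort()))
}

# Independent EDF byte writer (fixed-layout header + int16 records), used to
# test the package's reader against bytes it did not produce.
write_edf_fixture <- function(path, signals, fs, labels = NULL) {
  ns <- ncol(signals)
  n <- nrow(signals)
  stopifnot(n %% fs == 0)
  n_rec <- n / fs
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(ns))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  phys_min <- -500; phys_max <- 500
  dig_min <- -32768; dig_max <- 32767
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("depth electrode", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(phys_min, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((signals - phys_min) / gain + dig_min)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[rows, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

# Brute-force union-find over interval nodes: the oracle for join_detections.
brute_force_components <- function(iv) {
  n <- nrow(iv)
  parent <- seq_len(n)
  find <- function(i) while (TRUE) {
    if (parent[i] == i) return(i)
    i <- parent[i]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(iv$band[i] - iv$band[j]) == 1 &&
        iv$t_start[i] < iv$t_end[j] && iv$t_start[j] < iv$t_end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}
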