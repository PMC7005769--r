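# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's own code paths (no rle(), no
# encode_runs()) so they can serve as cross-checks.

Q8 <- c("H", "G", "I", "E", "B", "T", "S", "C")

# run scanner by explicit loop: list of (label, length)
brute_runs <- function(labels) {
  out <- list()
  cur <- labels[1]
  len <- 1L
  for (x in labels[-1]) {
    if (x == cur) {
      len <- len + 1L
    } else {
      out[[length(out) + 1L]] <- list(label = cur, length = len)
      cur <- x
      len <- 1L
    }
  }
  out[[length(out) + 1L]] <- list(label = cur, length = len)
  out
}

brute_run_count <- function(labels) length(brute_runs(labels))

# long label-trajectory tibble from a frames x residues character matrix
traj_from_matrix <- function(m, residue_ids = seq_len(ncol(m)),
                             times = 200 * (seq_len(nrow(m)) - 1)) {
  tibble::tibble(
    frame = rep(seq_len(nrow(m)), each = ncol(m)),
    time_ps = rep(times, each = ncol(m)),
    residue_id = rep(residue_ids, times = nrow(m)),
    label = as.vector(t(m))
  )
}

# classic DSSP fixture: residue rows with author numbering, chain, amino
# acid at column 14 and structure code at column 17
write_dssp_fixture <- function(path, resnum, aa, code, chain = "A") {
  n <- length(resnum)
  chain <- rep_len(chain, n)
  rows <- vapply(seq_len(n), function(i) {
    if (aa[i] == "!") {
      sprintf("%5d      %1s %1s", i, " ", "!")
    } else {
      sprintf("%5d%5d %1s %1s  %1s", i, resnum[i], chain[i], aa[i], code[i])
    }
  }, character(1))
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    rows
  ), path)
  path
}

# residue positions covered by a region tibble
region_residues <- function(r) {
  if (nrow(r) == 0) return(integer(0))
  unique(unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i])))
}

# population used for the bin-trend checks: chains spanning low to high
# structured content, flexibility tied to coil content
bin_population <- function(n = 100, seed = 500) {
  purrr::map_dfr(seq_len(n), function(j) {
    t <- (j - 1) / (n - 1)
    sim <- sim_reference(
      length = 200,
      coil_run_mean = 1 + 9 * (1 - t),
      helix_run_mean = 4 + 6 * t,
      beta_run_mean = 3 + 3 * t,
      mix = c(helix = 0.6, beta = 0.4),
      seed = seed + j
    )
    pred <- sim_predictions(sim$reference, sim$phi, seed = seed + 1000 + j)
    dplyr::mutate(
      order_score(sim$reference$label, protein_id = sprintf("p%03d", j)),
      accuracy = protein_accuracy(pred, sim$reference$label)
    )
  })
}

# the planted-blocks fixture used for region-recovery checks: three
# flexible blocks on an otherwise rigid 200-residue chain, a 200-frame
# label trajectory in which flexible residues change state every ~10
# frames while rigid residues rarely change, and disorder predictors
# blind to the middle block
recovery_fixture <- function(seed = 42) {
  planted <- tibble::tibble(start = c(30L, 90L, 150L), end = c(50L, 110L, 170L))
  sim <- sim_reference(
    length = 200, seed = seed,
    planted_regions = planted, coil_flexible = FALSE
  )
  traj <- sim_trajectory(
    sim$reference, sim$phi,
    n_frames = 200, f_min = 0, f_max = 0.05, seed = seed + 1
  )
  disorder <- sim_disorder(
    sim$phi,
    blind_regions = planted[2, , drop = FALSE], seed = seed + 2
  )
  list(sim = sim, planted = planted, traj = traj, disorder = disorder,
       blind = planted[2, , drop = FALSE])
}
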