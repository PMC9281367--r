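# Small free-energy-profile fixtures built in code.

# Single-barrier unimolecular reaction: S -> (S ts) -> P.
profile_single <- function(G = c(0, 18, -3), branch = "unbound") {
  free_energy_profile(
    data.frame(name = c("S", "S_ts", "P"),
               kind = c("ground", "barrier", "ground"),
               G = G),
    branch = branch)
}

# Two-route profile laid out along one coordinate:
# P1 <- (ts1) <- S -> (ts2) -> P2, encoded as an alternating ladder.
profile_two_route <- function(G = c(-3, 17, 0, 15, -5), branch = "unbound") {
  free_energy_profile(
    data.frame(name = c("P1", "ts1", "S", "ts2", "P2"),
               kind = c("ground", "barrier", "ground", "barrier", "ground"),
               G = G),
    branch = branch)
}

shift_states <- function(profile, by, shift) {
  st <- profile$states
  st$G[st$name %in% by] <- st$G[st$name %in% by] + shift
  free_energy_profile(st, branch = "bound")
}
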