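# evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream (so seeded helpers can be used inside the caller's own replicate
# loops without collapsing them onto one draw)
with_seed <- function(seed, expr) {
  force(seed)  # the seed expression may itself consume the caller's RNG
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}
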