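# Shared heavy objects, built once per test run. The full 306-channel
# array with its multipole basis and leadfields takes a few seconds; most
# tests reuse it through these accessors.
.shared <- new.env(parent = emptyenv())

get_array <- function() {
  if (is.null(.shared$array)) .shared$array <- build_array()
  .shared$array
}

get_space <- function() {
  if (is.null(.shared$space)) .shared$space <- build_source_space()
  .shared$space
}

# Unpruned basis: the exact algebraic object of the separation model.
get_basis_raw <- function() {
  if (is.null(.shared$basis_raw))
    .shared$basis_raw <- assemble_basis(get_array())
  .shared$basis_raw
}

# Condition-limited basis as used by the experiment pipeline.
get_basis <- function() {
  if (is.null(.shared$basis))
    .shared$basis <- assemble_basis(get_array(), prune_condition = 100)
  .shared$basis
}

get_leadfield <- function() {
  if (is.null(.shared$lf))
    .shared$lf <- compute_leadfield(get_array(), get_space())
  .shared$lf
}

get_leadfield_proj <- function() {
  if (is.null(.shared$lf_proj))
    .shared$lf_proj <- project_leadfield(get_leadfield(), get_basis())
  .shared$lf_proj
}

# A small helper: render one resting subject and return raw + cleaned data.
render_subject <- function(seed, duration = 30, interference = "high") {
  sc <- make_resting_scene(seed, 1, interference, duration = duration,
                           space = get_space())[[1]]
  M <- render(sc, get_array(), leadfield = get_leadfield())
  list(scene = sc, raw = M,
       sss = sss_separate(M, get_basis()))
}

pipeline_setup <- function() {
  if (is.null(.shared$pipe_setup)) {
    .shared$pipe_setup <- list(array = get_array(), space = get_space(),
                               basis = get_basis(), lf = get_leadfield(),
                               lf_proj = get_leadfield_proj())
  }
  .shared$pipe_setup
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(abs(b)), tol)
}
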