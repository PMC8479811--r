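# fixtures are deterministic; cache them per test run
.fx_cache <- new.env(parent = emptyenv())

fx <- function(nm) {
  if (is.null(.fx_cache[[nm]])) .fx_cache[[nm]] <- make_fixture(nm)
  .fx_cache[[nm]]
}
fx_top <- function(nm) fx(nm)$top
fx_coords <- function(nm) fx(nm)$coords
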