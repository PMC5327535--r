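# Shared fixtures: small parameter objects and populations built in code.

tp_default <- function(...) trait_params(...)

# a fish population built directly from vectors/matrices (bypassing
# introduction) for unit tests of demography and genetics
make_test_population <- function(bO, female = NULL, age = NULL,
                                 gA = NULL, gB = NULL, nll = 8L) {
  n <- length(bO)
  if (is.null(female)) female <- rep(c(TRUE, FALSE), length.out = n)
  if (is.null(age)) age <- rep(3L, n)
  ones <- matrix(1L, n, nll)
  zeros <- matrix(0L, n, nll)
  pop <- alewifesim:::new_fish_population(
    female = female, age = age, bO = bO,
    gA1 = if (is.null(gA)) ones else gA[[1]],
    gA2 = if (is.null(gA)) ones else gA[[2]],
    gB1 = if (is.null(gB)) zeros else gB[[1]],
    gB2 = if (is.null(gB)) zeros else gB[[2]])
  pop$mature <- rep(TRUE, n)
  pop
}

# reproduce() warns when there are mature females but no mature males; most
# tests want the empty result silently
quiet_reproduce <- function(...) suppressWarnings(reproduce(...))
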