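# Shared fixture handling and independent oracles.

.fixtureCache <- new.env(parent = emptyenv())

# generate (once per session) and return the path of a named fixture
fixturePath <- function(name, d = 4.0) {
  key <- paste0(name, "_", d)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  dir <- file.path(tempdir(), "ifmap-fixtures", key)
  p <- makeFixture(name, dir, d = d)
  .fixtureCache[[key]] <- p
  p
}

fixtureModel <- function(name, d = 4.0) {
  selectFirstModel(readStructure(fixturePath(name, d)))
}

fixtureSelection <- function(name, chain1 = "A", chain2 = "B", d = 4.0) {
  m <- fixtureModel(name, d)
  resolveSelection(m, regionSelection(chain1), regionSelection(chain2))
}

# Exhaustive O(n^2) contact oracle, independent of the grid search.
bruteForcePairs <- function(a, b, cutoff) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d <= cutoff) out[[length(out) + 1]] <- c(i, j, d)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      d = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), d = m[, 3])
}

# Run a short python program and return its stdout lines.
runPython <- function(code) {
  system2("python", "-", input = code, stdout = TRUE, stderr = FALSE)
}

xyzOf <- function(model, idx = seq_len(nAtoms(model))) {
  as.matrix(atoms(model)[idx, c("x", "y", "z")])
}
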