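# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small textured phantom with bone, 1 mm pixels (30 mm discs -> 15 px radius)
small_phantom <- function() memo_fixture("ph96",
  generate_phantom(phantom_spec(image_size = 96, spacing_mm = 1, seed = 11)))

medium_phantom <- function() memo_fixture("ph128",
  generate_phantom(phantom_spec(image_size = 128, spacing_mm = 1, seed = 12)))

# piecewise-constant phantoms: no texture, no organs, no bone
flat_phantom <- function() memo_fixture("flat96",
  generate_phantom(phantom_spec(image_size = 96, spacing_mm = 1,
                                n_organs = 0, texture_amplitude_hu = 0,
                                bone = FALSE, seed = 13)))

flat_phantom_big <- function() memo_fixture("flat128",
  generate_phantom(phantom_spec(image_size = 128, spacing_mm = 1,
                                n_organs = 0, texture_amplitude_hu = 0,
                                bone = FALSE, seed = 14)))

# fast simulator settings for unit tests
test_sim_config <- function(seed = 5)
  noise_sim_config(n_angles = 120, seed = seed)

# centred elliptical mask safely inside the torso (discs placed from it
# stay clear of the body edge)
inner_torso_mask <- function(ph, scale = 0.55) {
  body <- attr(ph, "body")
  n <- nrow(body)
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  c0 <- (n + 1) / 2
  inner <- ((jj - c0) / (scale * 0.42 * n))^2 +
    ((ii - c0) / (scale * 0.32 * n))^2 <= 1
  region_mask(inner & body, role = "torso")
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  unname(p)
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- system2(python_bin(), f, stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}
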