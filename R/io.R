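#' Read and write FSL-style gradient tables
#'
#' `bvals` is a single whitespace-separated row of b-values (s/mm^2);
#' `bvecs` holds three rows (x, y, z components), with unit columns for
#' diffusion-weighted entries and zero columns for baselines.  Non-unit
#' vectors are normalized on read with a warning.  Writing then reading
#' reproduces the table up to float formatting.
#'
#' @param prefix path prefix; files are `<prefix>.bval` and
#'   `<prefix>.bvec`.
#' @param table a [gradient_table()] (for writing).
#' @return `read_gradient_table` returns a [gradient_table()];
#'   `write_gradient_table` returns the prefix invisibly.
#' @export
read_gradient_table <- function(prefix) {
  fb <- paste0(prefix, ".bval"); fv <- paste0(prefix, ".bvec")
  if (!file.exists(fb) || !file.exists(fv))
    stop("missing gradient table file(s): ", fb, " / ", fv)
  b <- scan(fb, quiet = TRUE)
  rows <- lapply(readLines(fv, warn = FALSE), function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  rows <- rows[vapply(rows, length, integer(1)) > 0]
  if (length(rows) != 3)
    stop("bvec file must have exactly 3 rows, found ", length(rows))
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("ragged bvec rows: lengths ", paste(lens, collapse = "/"))
  if (lens[1] != length(b))
    stop("bval has ", length(b), " entries but bvec has ", lens[1],
         " columns")
  dirs <- t(do.call(rbind, rows))
  if (any(!is.finite(b)) || any(!is.finite(dirs)))
    stop("NaN/Inf in gradient table")
  gradient_table(b, dirs)
}

#' @rdname read_gradient_table
#' @export
write_gradient_table <- function(table, prefix) {
  stopifnot(inherits(table, "gradient_table"))
  writeLines(paste(.fmt(table$b), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(table$dirs), 1, function(r)
    paste(.fmt(r), collapse = " ")), paste0(prefix, ".bvec"))
  invisible(prefix)
}

.fmt <- function(x) formatC(x, format = "g", digits = 17)

#' Read and write EAP coefficient files
#'
#' Plain-text JSON round-trip of the two coefficient formats: MAP-MRI
#' coefficients with their explicit `(n1, n2, n3)` index list plus the
#' frame `(U, sx, sy, sz, tau)`, and SH fODF coefficients (flat array
#' in canonical l-ascending, m = -l..l order with `L` in the header)
#' plus the axisymmetric kernel eigenvalues and `tau`.
#'
#' @param eap a [mapmri_eap()] or [sc_eap()] (for writing).
#' @param path JSON file path.
#' @return `read_eap` returns the reconstructed EAP object;
#'   `write_eap` returns `path` invisibly.
#' @export
write_eap <- function(eap, path) {
  if (inherits(eap, "mapmri_eap")) {
    obj <- list(format = "mapmri", Nmax = eap$Nmax,
                index = eap$index, a = eap$a,
                scales = eap$scales, U = eap$U, tau = eap$tau)
  } else if (inherits(eap, "sc_eap")) {
    obj <- list(format = "sh_fodf", L = eap$fodf$L,
                phi = eap$fodf$phi,
                lambda_par = eap$lambda_par,
                lambda_perp = eap$lambda_perp, tau = eap$tau)
  } else if (inherits(eap, "diffusion_tensor")) {
    obj <- list(format = "tensor", D = eap$D)
  } else stop("unsupported EAP class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eap
#' @export
read_eap <- function(path) {
  if (!file.exists(path)) stop("missing EAP file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$format,
    mapmri = mapmri_eap(
      data.frame(n1 = obj$index$n1, n2 = obj$index$n2,
                 n3 = obj$index$n3, a = obj$a),
      Nmax = obj$Nmax, scales = obj$scales,
      U = matrix(unlist(obj$U), 3, 3), tau = obj$tau),
    sh_fodf = sc_eap(sh_coefficients(obj$phi, obj$L),
                     obj$lambda_par, obj$lambda_perp, obj$tau),
    tensor = diffusion_tensor(matrix(unlist(obj$D), 3, 3)),
    stop("unknown EAP format: ", obj$format))
}

#' Read and write DWI stacks as a text container
#'
#' The stack is stored as two full-precision CSV matrices (real and
#' imaginary signal channels, voxels x entries), a voxel coordinate
#' CSV, the gradient table, and a JSON manifest carrying the gradient
#' association, spin count, seed and package version.  The round trip
#' is lossless for float64 payloads.  If the `RNifti` package is
#' available a 4-D magnitude NIfTI can additionally be written with
#' `nifti = TRUE` (never required by any computation).
#'
#' @param stack a `dwi_stack` (for writing).
#' @param dir directory to write into / read from.
#' @param nifti also write `magnitude.nii.gz` (requires RNifti).
#' @return `read_dwi_stack` returns a `dwi_stack`; `write_dwi_stack`
#'   returns `dir` invisibly.
#' @export
write_dwi_stack <- function(stack, dir, nifti = FALSE, extra = list()) {
  stopifnot(inherits(stack, "dwi_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_mat(Re(stack$signal), file.path(dir, "signal_real.csv"))
  .write_mat(Im(stack$signal), file.path(dir, "signal_imag.csv"))
  utils::write.csv(stack$voxels, file.path(dir, "voxels.csv"),
                   row.names = FALSE)
  write_gradient_table(stack$table, file.path(dir, "gradients"))
  manifest <- list(format = "eapsim_dwi_stack", axis_order = "voxel,entry",
                   n_voxels = nrow(stack$signal),
                   n_entries = ncol(stack$signal),
                   baseline_index = stack$baseline_index,
                   spins_per_voxel = stack$spins_per_voxel,
                   preset = stack$preset, seed = stack$seed,
                   version = as.character(utils::packageVersion("eapsim")))
  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nifti) .write_nifti_magnitude(stack, dir)
  invisible(dir)
}

.write_mat <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(.fmt(r), collapse = ",")),
             path)
}

.read_mat <- function(path) {
  rows <- lapply(readLines(path, warn = FALSE), function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]]))
  do.call(rbind, rows)
}

.write_nifti_magnitude <- function(stack, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    warning("RNifti not available; skipping NIfTI export")
    return(invisible(NULL))
  }
  v <- stack$voxels
  arr <- array(0, dim = c(max(v$ix), max(v$iy), 1, ncol(stack$signal)))
  for (j in seq_len(ncol(stack$signal)))
    arr[cbind(v$ix, v$iy, 1, j)] <- abs(stack$signal[, j])
  RNifti::writeNifti(RNifti::asNifti(arr),
                     file.path(dir, "magnitude.nii.gz"))
}

#' @rdname write_dwi_stack
#' @export
read_dwi_stack <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("missing manifest.json in ", dir, "; refusing to guess the layout")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  re <- .read_mat(file.path(dir, "signal_real.csv"))
  im <- .read_mat(file.path(dir, "signal_imag.csv"))
  table <- read_gradient_table(file.path(dir, "gradients"))
  if (ncol(re) != length(table$b) || ncol(re) != manifest$n_entries ||
      nrow(re) != manifest$n_voxels)
    stop("manifest/stack mismatch in ", dir)
  structure(list(signal = matrix(complex(real = re, imaginary = im),
                                 nrow(re), ncol(re)),
                 table = table,
                 voxels = utils::read.csv(file.path(dir, "voxels.csv")),
                 preset = manifest$preset,
                 baseline_index = manifest$baseline_index,
                 spins_per_voxel = manifest$spins_per_voxel,
                 seed = manifest$seed,
                 sampler_info = NULL),
            class = "dwi_stack")
}

#' Write and read a phantom specification
#'
#' JSON serialization of a [make_fiber_field()] result (grid, voxels,
#' tissue maps and every EAP).
#'
#' @param phantom a `phantom_spec`.
#' @param path JSON file path.
#' @return `read_phantom` returns the `phantom_spec`; `write_phantom`
#'   returns `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  eaps <- lapply(phantom$eaps, function(e) {
    if (inherits(e, "diffusion_tensor")) list(format = "tensor", D = e$D)
    else if (inherits(e, "mapmri_eap"))
      list(format = "mapmri", Nmax = e$Nmax, index = as.list(e$index),
           a = e$a, scales = e$scales, U = e$U, tau = e$tau)
    else list(format = "sh_fodf", L = e$fodf$L, phi = e$fodf$phi,
              lambda_par = e$lambda_par, lambda_perp = e$lambda_perp,
              tau = e$tau)
  })
  obj <- list(format = "eapsim_phantom", dims = phantom$dims,
              spacing = phantom$spacing, preset = phantom$preset,
              seed = phantom$seed, voxels = as.list(phantom$voxels),
              tissue = as.list(phantom$tissue), eaps = eaps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  if (!file.exists(path)) stop("missing phantom file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  num <- function(x) as.numeric(unlist(x))
  eaps <- lapply(obj$eaps, function(e) {
    switch(e$format,
      tensor = diffusion_tensor(matrix(num(e$D), 3, 3)),
      mapmri = mapmri_eap(
        data.frame(n1 = num(e$index$n1), n2 = num(e$index$n2),
                   n3 = num(e$index$n3), a = num(e$a)),
        Nmax = e$Nmax, scales = num(e$scales),
        U = matrix(num(e$U), 3, 3), tau = e$tau),
      sh_fodf = sc_eap(sh_coefficients(num(e$phi), e$L), e$lambda_par,
                       e$lambda_perp, e$tau),
      stop("unknown EAP format"))
  })
  structure(list(dims = num(obj$dims), spacing = obj$spacing,
                 preset = obj$preset, seed = obj$seed,
                 voxels = as.data.frame(lapply(obj$voxels, unlist)),
                 eaps = eaps,
                 tissue = as.data.frame(lapply(obj$tissue, unlist))),
            class = "phantom_spec")
}
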