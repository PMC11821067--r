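#' Write a scene set as delimited text
#'
#' One file per scene (`scene_<id>.txt`, columns `wavelength_nm`, `E`, `R`,
#' `SIF_true`) plus a `manifest.txt` mapping scene ids to parameters.
#'
#' @param scenes scene table from [generate_lut()].
#' @param dir output directory (created if missing).
#' @param grid wavelength grid for the spectra.
#' @param sep field separator.
#' @return invisibly, the manifest path.
#' @export
write_scene_set <- function(scenes, dir, grid = native_grid(650, 815, 0.5),
                            sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(scenes))) {
    sc <- scenes[i, ]
    cs <- canopy_spectra(sc, grid)
    e <- solar_irradiance(atmosphere_spec(sc$wvc_g_cm2), grid, sc$sza_deg)
    df <- data.frame(wavelength_nm = grid, E = e$values, R = cs$R$values,
                     SIF_true = cs$SIF$values)
    utils::write.table(df, file.path(dir, sprintf("scene_%04d.txt", sc$scene_id)),
                       sep = sep, row.names = FALSE, quote = FALSE)
  }
  mf <- file.path(dir, "manifest.txt")
  utils::write.table(scenes, mf, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(mf)
}

#' Read a scene set written by [write_scene_set()]
#'
#' Column names can be remapped through `col_map` so externally exported
#' spectra (plain-column text) can be read with the same layout.
#'
#' @param dir directory holding `scene_*.txt` files and `manifest.txt`.
#' @param sep field separator.
#' @param col_map named character vector mapping the expected columns
#'   (`wavelength_nm`, `E`, `R`, `SIF_true`) to those present in the files.
#' @return list with `manifest` (data frame) and `scenes` (named list per
#'   scene of `E`, `R`, `SIF` [spectrum()]s).
#' @export
read_scene_set <- function(dir, sep = "\t",
                           col_map = c(wavelength_nm = "wavelength_nm",
                                       E = "E", R = "R",
                                       SIF_true = "SIF_true")) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop("no manifest.txt in ", dir)
  manifest <- utils::read.table(mf, header = TRUE, sep = sep)
  files <- sort(list.files(dir, pattern = "^scene_\\d+\\.txt$",
                           full.names = TRUE))
  scenes <- lapply(files, function(f) {
    df <- utils::read.table(f, header = TRUE, sep = sep)
    if (!all(col_map %in% names(df)))
      stop("missing columns in ", f, ": ",
           paste(setdiff(col_map, names(df)), collapse = ", "))
    wl <- df[[col_map["wavelength_nm"]]]
    list(E = spectrum(wl, df[[col_map["E"]]], "irradiance"),
         R = spectrum(wl, df[[col_map["R"]]], "reflectance"),
         SIF = spectrum(wl, df[[col_map["SIF_true"]]], "radiance"))
  })
  names(scenes) <- sub("\\.txt$", "", basename(files))
  list(manifest = manifest, scenes = scenes)
}
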