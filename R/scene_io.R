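# Scene description files (JSON): regions with shapes and material names.

.shape_from_json <- function(s) {
  switch(s$type,
    box = shape_box(s$lower, s$upper),
    cylinder_shell = shape_cylinder(s$base, s$axis, s$r_outer, s$height,
                                    s$r_inner %||% 0),
    sphere_shell = shape_sphere(s$center, s$r_outer, s$r_inner %||% 0,
                                s$axis %||% c(0, 0, 1), s$h_range),
    stop("unknown shape type: ", s$type))
}

.shape_to_json <- function(sh) {
  switch(sh$type,
    box = list(type = "box", lower = sh$lower / M2CM, upper = sh$upper / M2CM),
    cylinder = list(type = "cylinder_shell", base = sh$base / M2CM,
                    axis = sh$axis, r_inner = sh$r_inner / M2CM,
                    r_outer = sh$r_outer / M2CM, height = sh$height / M2CM),
    sphere = list(type = "sphere_shell", center = sh$center / M2CM,
                  axis = sh$axis, r_inner = sh$r_inner / M2CM,
                  r_outer = sh$r_outer / M2CM, h_range = sh$h_range / M2CM))
}

#' Read / write scene descriptions (JSON)
#'
#' The schema carries `ambient` (material name) and `regions`, each with
#' `name`, `material`, `priority` and a `shape` object (`type` one of
#' `box`, `cylinder_shell`, `sphere_shell`; dimensions in metres).
#'
#' @param path file path.
#' @param materials material library for name resolution.
#' @return a [scene_model()].
#' @export
read_scene_json <- function(path, materials = material_library()) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  regions <- lapply(j$regions, function(r)
    region(.shape_from_json(r$shape), r$material,
           priority = r$priority %||% 1L, name = r$name))
  sc <- scene_model(regions, ambient = j$ambient %||% "air",
                    materials = materials)
  attr(sc, "dimensions") <- j$dimensions
  sc
}

#' @rdname read_scene_json
#' @param scene a [scene_model()].
#' @export
write_scene_json <- function(scene, path) {
  body <- list(
    ambient = scene$ambient,
    regions = lapply(scene$regions, function(r) list(
      name = r$name, material = r$material, priority = r$priority,
      shape = .shape_to_json(r$shape))))
  if (!is.null(attr(scene, "dimensions")))
    body$dimensions <- attr(scene, "dimensions")
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
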