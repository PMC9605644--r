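# Small, fast fixture builders shared across test files.

# a scaled-down synthetic sequence for I/O and orchestration tests (the
# full-size default geometry is exercised in the end-to-end tests)
small_synth_config <- function(n_frames = 6, kind = "growth", seed = 7) {
  synthetic_config(height = 96L, width = 96L, n_frames = n_frames,
                   kind = kind, cell_radius_range = c(10, 16), seed = seed)
}

make_gray_frame <- function(mat, index = 0L) {
  gema_frame(mat, index = index, source_name = sprintf("test_%03d.png", index))
}

via_polygon_region <- function(xs, ys) {
  sprintf('{"shape_attributes":{"name":"polygon","all_points_x":[%s],"all_points_y":[%s]},"region_attributes":{"type":"cell"}}',
          paste(xs, collapse = ","), paste(ys, collapse = ","))
}

# region-list export dialect: top level keyed by filename + size
via_region_export <- function(filename, regions) {
  sprintf('{"%s12345":{"filename":"%s","size":12345,"regions":[%s],"file_attributes":{}}}',
          filename, filename, paste(regions, collapse = ","))
}

# project-file dialect: same entries nested under _via_img_metadata
via_project_export <- function(filename, regions) {
  sprintf('{"_via_settings":{"ui":{}},"_via_img_metadata":%s,"_via_attributes":{}}',
          via_region_export(filename, regions))
}

write_tempfile <- function(text, ext = ".json") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}
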