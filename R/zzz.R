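# Built-in driver tools.  Registered at load time so the loop driver and
# the CLI can refer to them by name.

register_builtin_tools <- function() {
  register_tool("copy", function(inputs, opts) inputs[[1]])
  register_tool("fft", function(inputs, opts) {
    if (is.null(opts$flags)) stop("fft tool needs opts$flags")
    inv <- isTRUE(opts$inverse) ||
      (is.numeric(opts$inverse) && opts$inverse != 0)
    fft_md(inputs[[1]], opts$flags, inverse = inv)
  })
  register_tool("rss", function(inputs, opts)
    rss_combine(inputs[[1]], coil_axis = opts$coil_axis %||% 2))
  register_tool("resize", function(inputs, opts) {
    if (is.null(opts$target)) stop("resize tool needs opts$target")
    resize_center(inputs[[1]], opts$target)
  })
  register_tool("ramlak", function(inputs, opts) {
    trj <- if (length(inputs) >= 2) inputs[[2]] else opts$trj
    ramlak_filter(array(inputs[[1]], dim = md_dims(inputs[[1]])[1:3]),
                  array(trj, dim = md_dims(trj)[1:3]))
  })
  register_tool("nufft", function(inputs, opts) {
    trj <- if (length(inputs) >= 2) inputs[[2]] else opts$trj
    if (is.null(opts$grid)) stop("nufft tool needs opts$grid")
    nufft_adjoint(array(inputs[[1]], dim = md_dims(inputs[[1]])[1:3]),
                  array(trj, dim = md_dims(trj)[1:3]), grid = opts$grid)
  })
  register_tool("nlm", function(inputs, opts) {
    d <- dim(inputs[[1]])
    res <- nlm_filter(inputs[[1]], patch = opts$patch %||% 5,
                      search = opts$search %||% 11, h = opts$h)
    array(as.complex(res), dim = d)
  })
  register_tool("median", median_tool_step, stream_aware = TRUE)
  register_tool("nlinv", function(state, inputs, opts) {
    trj <- if (length(inputs) >= 2) inputs[[2]] else opts$trj
    cfg <- opts$config %||% nlinv_config()
    res <- nlinv_frame(array(inputs[[1]], dim = md_dims(inputs[[1]])[1:3]),
                       array(trj, dim = md_dims(trj)[1:3]),
                       grid = opts$grid, config = cfg, state = state)
    list(state = res$state,
         output = array(res$image, dim = c(opts$grid, opts$grid, 1)))
  }, stream_aware = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_tools()
}
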