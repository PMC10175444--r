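# Solar elevation (degrees) from latitude, day of year and local solar
# hour, using the simple Cooper declination formula. Good to ~1 degree,
# ample for day/night masking and diurnal PAR shaping.
solar_elevation <- function(timestamp, latitude) {
  doy <- lubridate::yday(timestamp)
  hour <- lubridate::hour(timestamp) + lubridate::minute(timestamp) / 60
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  h_angle <- 15 * (hour - 12)
  rad <- pi / 180
  sin_elev <- sin(latitude * rad) * sin(decl * rad) +
    cos(latitude * rad) * cos(decl * rad) * cos(h_angle * rad)
  asin(pmin(1, pmax(-1, sin_elev))) / rad
}
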