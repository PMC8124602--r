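// Minimal grayscale PNG codec (bit depth 8 or 16, colour type 0).
//
// No PNG package is available in the target library, so the small subset of
// the format needed for depth maps (single IDAT written by us; any mix of
// scanline filters 0-4 on read) is implemented directly on top of zlib.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>

using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static uint32_t get_u32(const unsigned char* p) {
  return ((uint32_t)p[0] << 24) | ((uint32_t)p[1] << 16) |
         ((uint32_t)p[2] << 8) | (uint32_t)p[3];
}

static void write_chunk(std::vector<unsigned char>& out, const char* type,
                        const std::vector<unsigned char>& data) {
  put_u32(out, (uint32_t)data.size());
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  out.insert(out.end(), data.begin(), data.end());
  uLong crc = crc32(0L, out.data() + start, (uInt)(out.size() - start));
  put_u32(out, (uint32_t)crc);
}

// [[Rcpp::export(name = ".png_write_gray")]]
void png_write_gray(std::string path, IntegerMatrix img, int bit_depth) {
  if (bit_depth != 8 && bit_depth != 16)
    stop("bit_depth must be 8 or 16");
  const int h = img.nrow(), w = img.ncol();
  const int maxv = bit_depth == 16 ? 65535 : 255;
  const int bpp = bit_depth / 8;

  std::vector<unsigned char> raw((size_t)h * (1 + (size_t)w * bpp));
  size_t k = 0;
  for (int r = 0; r < h; ++r) {
    raw[k++] = 0;  // filter type: none
    for (int c = 0; c < w; ++c) {
      int v = img(r, c);
      if (v == NA_INTEGER || v < 0 || v > maxv)
        stop("pixel value out of range [0, %d] at row %d col %d", maxv, r + 1, c + 1);
      if (bpp == 2) raw[k++] = (v >> 8) & 0xff;
      raw[k++] = v & 0xff;
    }
  }

  uLongf zlen = compressBound((uLong)raw.size());
  std::vector<unsigned char> zbuf(zlen);
  if (compress2(zbuf.data(), &zlen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  zbuf.resize(zlen);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);

  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)w);
  put_u32(ihdr, (uint32_t)h);
  ihdr.push_back((unsigned char)bit_depth);
  ihdr.push_back(0);  // colour type 0: grayscale
  ihdr.push_back(0);  // compression
  ihdr.push_back(0);  // filter method
  ihdr.push_back(0);  // no interlace
  write_chunk(out, "IHDR", ihdr);
  write_chunk(out, "IDAT", zbuf);
  write_chunk(out, "IEND", std::vector<unsigned char>());

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t n = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (n != out.size()) stop("short write to '%s'", path.c_str());
}

static int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export(name = ".png_read_gray")]]
List png_read_gray(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long fsize = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)fsize);
  size_t nread = std::fread(buf.data(), 1, (size_t)fsize, f);
  std::fclose(f);
  if (nread != (size_t)fsize) stop("short read from '%s'", path.c_str());

  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (fsize < 8 || memcmp(buf.data(), sig, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  size_t pos = 8;
  uint32_t w = 0, h = 0;
  int bit_depth = 0, colour = -1;
  std::vector<unsigned char> idat;
  bool seen_ihdr = false;
  while (pos + 12 <= (size_t)fsize) {
    uint32_t len = get_u32(&buf[pos]);
    std::string type((const char*)&buf[pos + 4], 4);
    if (pos + 12 + len > (size_t)fsize) stop("corrupt PNG chunk in '%s'", path.c_str());
    const unsigned char* data = &buf[pos + 8];
    if (type == "IHDR") {
      w = get_u32(data);
      h = get_u32(data + 4);
      bit_depth = data[8];
      colour = data[9];
      if (data[12] != 0) stop("interlaced PNG not supported");
      seen_ihdr = true;
    } else if (type == "IDAT") {
      idat.insert(idat.end(), data, data + len);
    } else if (type == "IEND") {
      break;
    }
    pos += 12 + len;
  }
  if (!seen_ihdr) stop("missing IHDR in '%s'", path.c_str());
  if (colour != 0)
    stop("expected a single-channel grayscale PNG (colour type 0), got colour type %d", colour);
  if (bit_depth != 8 && bit_depth != 16)
    stop("expected 8- or 16-bit grayscale PNG, got bit depth %d", bit_depth);

  const int bpp = bit_depth / 8;
  const size_t stride = 1 + (size_t)w * bpp;
  std::vector<unsigned char> raw(stride * h);
  uLongf rawlen = (uLongf)raw.size();
  if (uncompress(raw.data(), &rawlen, idat.data(), (uLong)idat.size()) != Z_OK ||
      rawlen != raw.size())
    stop("zlib decompression of '%s' failed", path.c_str());

  // undo scanline filtering in place
  for (uint32_t r = 0; r < h; ++r) {
    unsigned char* row = &raw[r * stride];
    unsigned char* prev = r > 0 ? &raw[(r - 1) * stride] : nullptr;
    int ft = row[0];
    unsigned char* cur = row + 1;
    unsigned char* up = prev ? prev + 1 : nullptr;
    size_t nb = (size_t)w * bpp;
    for (size_t i = 0; i < nb; ++i) {
      int a = i >= (size_t)bpp ? cur[i - bpp] : 0;
      int b = up ? up[i] : 0;
      int c = (up && i >= (size_t)bpp) ? up[i - bpp] : 0;
      int x = cur[i];
      switch (ft) {
        case 0: break;
        case 1: x = (x + a) & 0xff; break;
        case 2: x = (x + b) & 0xff; break;
        case 3: x = (x + (a + b) / 2) & 0xff; break;
        case 4: x = (x + paeth(a, b, c)) & 0xff; break;
        default: stop("unsupported PNG filter type %d", ft);
      }
      cur[i] = (unsigned char)x;
    }
  }

  IntegerMatrix img((int)h, (int)w);
  for (uint32_t r = 0; r < h; ++r) {
    const unsigned char* cur = &raw[r * stride] + 1;
    for (uint32_t c = 0; c < w; ++c) {
      int v = bpp == 2 ? ((int)cur[2 * c] << 8) | cur[2 * c + 1] : cur[c];
      img((int)r, (int)c) = v;
    }
  }
  return List::create(_["image"] = img, _["bit_depth"] = bit_depth);
}

// [[Rcpp::export(name = ".crc32_bytes")]]
double crc32_bytes(RawVector bytes) {
  uLong crc = crc32(0L, bytes.length() ? RAW(bytes) : nullptr, (uInt)bytes.length());
  return (double)crc;
}
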