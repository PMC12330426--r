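component_id,network
IC69,SCN
IC53,SCN
IC98,SCN
IC99,SCN
IC45,SCN
IC21,AUD
IC56,AUD
IC03,SMN
IC09,SMN
IC02,SMN
IC11,SMN
IC27,SMN
IC54,SMN
IC66,SMN
IC80,SMN
IC72,SMN
IC16,VSN
IC05,VSN
IC62,VSN
IC15,VSN
IC12,VSN
IC93,VSN
IC20,VSN
IC08,VSN
IC77,VSN
IC68,CCN
IC33,CCN
IC43,CCN
IC70,CCN
IC61,CCN
IC55,CCN
IC63,CCN
IC79,CCN
IC84,CCN
IC96,CCN
IC88,CCN
IC48,CCN
IC81,CCN
IC37,CCN
IC67,CCN
IC38,CCN
IC83,CCN
IC32,DMN
IC40,DMN
IC23,DMN
IC71,DMN
IC17,DMN
IC51,DMN
IC94,DMN
IC13,CBN
IC18,CBN
IC04,CBN
IC07,CBN
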