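{
  "type": "FeatureCollection",
  "note": "Synthetic coarse rectangles standing in for the Mississippi and Alabama state boundaries. For containment-logic testing only; not cartographic data.",
  "features": [
    {
      "type": "Feature",
      "properties": { "region_id": "MS", "name": "Mississippi (synthetic rectangle)" },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [ [-91.65, 30.2], [-88.4, 30.2], [-88.4, 35.0], [-91.65, 35.0], [-91.65, 30.2] ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": { "region_id": "AL", "name": "Alabama (synthetic rectangle)" },
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [ [-88.4, 30.2], [-84.9, 30.2], [-84.9, 35.0], [-88.4, 35.0], [-88.4, 30.2] ]
        ]
      }
    }
  ]
}
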